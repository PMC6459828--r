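---
title: "Serial qMRI of loaded cartilage: models, simulation and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial qMRI of loaded cartilage: models, simulation and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmricart)
```

## The problem

Early cartilage degeneration alters how the tissue responds to mechanical
load before resting (unloaded) imaging can reliably separate intact from
degenerative tissue. The experiment this package models images an
8 mm × 3 mm chondral disc seated in an artificial knee joint at three
displacement positions — unloaded (δ0), 2.5 mm (δ2.5) and 5.0 mm (δ5.0) of
tibial displacement — and maps four relaxation-time parameters (T1, T1ρ, T2,
T2\*) at each position. The analysis asks two questions: (i) which zonal
parameter changes under loading are statistically robust within each
histological group, and (ii) how well unloaded values, relative changes
(Δ2.5, Δ5.0) and their combinations separate intact (Mankin sum score 0–4)
from early degenerative (5–8) tissue.

`qmricart` re-implements this pipeline end to end, driven by a synthetic
cohort generator, because the original 49 patient samples are not publicly
deposited. Every stage is testable without any download.

## Signal models and fitting

T1ρ, T2 and T2\* decay mono-exponentially over their time dimension
(spin-lock duration or echo time):

$$S(t) = S_0\, e^{-t/T_c}.$$

T1 is measured by inversion recovery. The acquisition protocol gives no
functional form, so the package adopts the standard magnitude model for IR
data at finite repetition time,

$$S(TI) = \left| S_0\,(1 - 2 e^{-TI/T_1} + e^{-TR/T_1}) \right|,$$

as the generator's forward model, and fits the polarity-restored
three-parameter signed model $A + B e^{-TI/T_1}$: every possible split index
between "still inverted" and "recovered" points is tried, and the split with
the lowest residual sum of squares wins. This is the conventional treatment
of magnitude IR data when TR is only a few times T1 (here TR = 3000 ms
against T1 ≈ 700–800 ms, so the recovery term is not negligible).

Both fits use variable projection: for a fixed time constant the amplitude
parameters are linear and solved in closed form, leaving a one-dimensional
search over the time constant (log-linear slope seed for the
mono-exponential kinds, a log-spaced grid seed for IR, then local
optimisation). This is deterministic, derivative-free at the user level, and
recovers noiseless self-generated signals to better than 1e-6 relative
error. Time constants are constrained to [1, 5000] ms; a fit pinned at a
bound is marked invalid rather than reported.

Point exclusion follows the acquisition rule: all points enter the T1 and
T1ρ fits (the TSL = 0 point is a listed spin-lock duration and is retained),
while for T2 and T2\* the first echo and any echo beyond 60 ms are dropped.
Fit quality is the R² adjusted to the degrees of freedom,
$1-(1-R^2)(n-1)/(n-p-1)$; pixels below an adjusted R² of 0.7 are invalid.
The source protocol states that fit quality was checked but not the cutoff;
0.7 is this package's configurable default. Degenerate signals (constant,
all zero, non-finite) are invalid pixels, never exceptions — downstream
zonal statistics tolerate invalid pixels and report their fraction.

## Regions of interest

Manual segmentation is replaced by the generator's ground-truth masks (or
externally supplied label images for real data). The depth axis is the image
row axis; the articular surface faces the image bottom by default
(configurable). Three rules mirror the original measurement conventions:

* **Boundary exclusion.** The top and bottom pixel of every mask column is
  removed before fitting statistics, to emulate the exclusion of
  partial-volume boundary pixels.
* **Equal two-zone partition.** Each column's remaining pixels are split
  into the half nearer the surface (superficial, sf) and the rest (deep,
  dp). The source describes "two equal zones" without saying whether the cut
  was per column or a straight horizontal line; per-column is chosen because
  it keeps the partition exact for curved outlines, and the odd-pixel
  tie-break (extra pixel to the deep zone) makes it deterministic with
  `count(sf) + count(dp) = count(ECS)` on every input.
* **Caliper geometry.** Height and width are the masked extents of the
  central column and row (bounding-box midpoint), in pixel units of
  0.375 mm, emulating the digital caliper measurement on morphological
  images. Quantisation is therefore ± one pixel.

## The synthetic cohort: what it emulates and what it does not

A phantom is a 2D mid-coronal stadium-shaped disc (8 mm × 3 mm at δ0) in an
80 × 80 image of a 30 mm field of view, surrounded by a hypointense
silicone layer and zero-signal background. True relaxation times are
piecewise-constant per zone: the published tables report only zonal means,
so no within-zone texture is asserted. Group distributions default to the
published zonal means ± SD at δ0 (e.g. intact superficial T2
46.4 ± 7.0 ms); loading responses are multiplicative per-(parameter, zone,
group) factors derived from the ratios of the published group means at δ2.5
and δ5.0 to those at δ0. Disc height scales deterministically by the
cohort-mean height changes (−6.1% at δ2.5, −15.6% at δ5.0); width is kept
constant, mirroring the non-significant width change in the source data.

Two stochastic layers sit on top:

* **Rician image noise**, σ configurable, default S0/50 (disc SNR ≈ 50 at
  full signal; the source reports no SNR, so this is a stated assumption).
  At zero signal the noise floor is Rayleigh with mean σ√(π/2), which the
  tests verify on background pixels.
* **Per-sample response variability**: each sample's shift factor is
  multiplied by exp(ε), ε ~ N(0, 0.12). The value 0.12 was fixed once,
  before any acceptance run, from the borderline significances in the
  published loading table (a ~5% deep-zone T1 change at n = 22 was
  non-significant, p = 0.062, while a ~6% change at n = 27 reached
  p = 0.003; both imply a within-subject SD of the log-response of roughly
  0.10–0.25). Without this layer the repeated-measures design would have
  zero within-subject error and every shift would be trivially significant.

Mankin subscores are drawn by choosing a target sum uniformly in the group's
range (intact 0–4, degenerative 5–8) and allocating it unit-by-unit across
the four subscores under their ceilings (6/3/4/1) — only the sum
distribution is constrained by the source. Young's modulus truths are
truncated normals (intact 0.55 ± 0.31 MPa, degenerative 0.35 ± 0.34 MPa),
and stress–strain curves are linear with additive stress noise on a strain
grid up to the 21% protocol maximum; the tangent fit is an ordinary
least-squares line over the 10–20% strain window (the "tangent" is read as a
secant on that window, the usual practice for quasi-static ramps).

What a green test on this cohort does **not** establish: realistic
within-zone spatial heterogeneity, susceptibility artefacts or B0/B1
effects, partial-volume blur beyond pixelation, stress relaxation during
acquisition, or the true biological covariance between parameters — the
generator draws parameters independently. Cohort-level agreement with the
published tables is therefore a consistency check of the pipeline, not a
re-derivation of the biology.

## Statistics

All qMRI analyses run on natural-log-transformed values (the base only
shifts constants), checked with the D'Agostino–Pearson omnibus normality
test implemented from the standard skewness and kurtosis transformations
(verified against an independent reference implementation to 10 decimals).

Longitudinal effects use one-way within-subject (repeated-measures) ANOVA
across the three displacement positions, with Tukey-adjusted pairwise
post-tests computed on the within-subject error term via the studentized
range distribution. No sphericity correction is applied by default — the
source reports none — but a Greenhouse–Geisser option exists and is tested.
Null simulations at n = 20 put the empirical type-I error at ~5% (the
acceptance suite bounds it at 6.5%).

Group comparisons are Student's (pooled-variance) two-sample t-tests on log
values; correlations are tie-corrected Spearman ρ with the t-approximation
p-value; significance is stratified at 0.05/0.01/0.001 with no additional
multiplicity correction across parameter–zone families, mirroring the
source analysis. The power computation inverts the exact noncentral-t power
of the two-sided two-sample t-test over increasing per-group n; at d = 0.8,
α = 0.05, power 0.9 it returns 34.

## Diagnostics

Reference intervals are mean ± SD of the intact group. "Positive" means
*reads intact*: a sample is positive iff its marker value lies inside the
interval (bounds inclusive, with a 1e-12 relative tolerance so zero-width
intervals survive log/exp round-trips). Sensitivity is the fraction of
histologically intact samples reading positive, specificity the fraction of
degenerative samples reading negative. The default interval scale is
logarithmic for raw parameter values, consistent with the global
log-transform policy; relative changes (which can be negative) always use
the linear scale. The published interval bounds themselves match neither the
linear nor the log construction of the printed summaries and are therefore
not an acceptance surface here.

Combined tests fold pairwise: believe-the-positive (panel positive if any
component is positive, maximising sensitivity) and believe-the-negative
(panel negative if any component is negative, maximising specificity). Both
rules are associative, so panels of k ≥ 2 tests are supported. Samples with
unclassifiable markers (e.g. an undefined Δ) are excluded from the 2×2
table and counted in the report. Mankin sums above 8 are labelled
out-of-study rather than degenerative: such tissue was excluded from the
cohort and the dichotomisation is undefined there.

## Numerical and design notes

* Optimiser tolerance 1e-9 on the 1-D time-constant search; noiseless
  recovery is ~1e-8 relative, well inside the 1e-4 test tolerance.
* The 85-point stress–strain grid has a 0.25% strain step so the 10% and
  20% window edges lie on the grid exactly.
* Image arrays are indexed (row, column) with row 1 at the image top; masks,
  zone labels and maps share this convention; pixel spacing is
  FOV/grid = 0.375 mm.
* A fixed seed in `cohort_config()` makes the entire cohort — arrays,
  curves, metadata — byte-identical across runs; the CLI writes the seed
  into every metadata export.
* Series I/O uses a plain-text TSV frame stack with a JSON sidecar (no
  binary container dependency); overlays are ASCII PPM images with a fixed
  0–2000 ms colour scale for T1.

## Known limitations

The generator is a stated world, not a fitted one: its defaults are the
published summary statistics plus the assumptions listed above, and the
acceptance suite checks reproduction of the qualitative response pattern
(T1 decreases in both groups, deep-zone T2 increases in the degenerative
group) rather than exact replication of every printed p-value, which would
require the original per-sample data. Inversion-recovery fitting assumes the
magnitude model; whether the original routine fitted magnitude or
polarity-restored data is unstated, and both behaviours are available.
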