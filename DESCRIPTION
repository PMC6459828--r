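Package: qmricart
Title: Serial Multiparametric qMRI Analysis of Articular Cartilage Under Loading
Version: 0.1.0
Authors@R: person("qmricart", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for serial quantitative MRI
    (T1, T1rho, T2, T2*) of articular cartilage imaged at successive
    compressive loading positions. Provides a synthetic phantom and cohort
    generator with Rician magnitude noise, pixel-wise mono-exponential and
    inversion-recovery relaxometry with echo-exclusion and fit-quality rules,
    zonal region-of-interest statistics with boundary erosion and equal
    two-zone partition, loading-response biomarkers (relative changes,
    Young's modulus from stress-strain curves), the associated statistical
    battery (log-transform normality checking, repeated-measures ANOVA with
    Tukey post-tests, unpaired t-tests, Spearman correlation, noncentral-t
    sample-size estimation), and reference-interval diagnostics with
    believe-the-positive / believe-the-negative test combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
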