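Package: icfmap
Title: Intracortical Facilitation TMS-EEG Mapping and Cell-Type Virtual Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven analysis pipeline for paired-pulse
    intracortical facilitation (ICF) TMS-EEG studies. Generates synthetic
    cohorts (epoched evoked EEG, leadfield-based source models, clinical
    covariates) with known ground truth; implements a deterministic EEG
    cleaning chain (baseline correction, robust bad-channel detection,
    amplitude-based epoch rejection, pulse-window excision with cubic
    interpolation, zero-phase filtering, spherical-spline channel
    interpolation, average reference); computes sensor-level evoked
    contrasts and local mean field power; estimates noise-normalized
    minimum-norm (dSPM) source activity with shrinkage noise covariance and
    extracts Desikan-Killiany region time series; runs group statistics
    (pooled t-tests, regional t-maps, clinical correlations); and tests
    cell-type-specific regional gene expression against the group
    difference map with a matched-size random-gene-set resampling null
    ("virtual histology"), including an exact enumeration oracle and
    Bonferroni reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
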