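Package: lungfilter
Title: Particle-Filter Staging of Longitudinal Lung-Nodule Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Sequential Monte Carlo (bootstrap particle filter) estimation of a
    latent malignancy score for lung nodules followed across CT screening
    intervals. Radiomic feature trajectories (surface-volume ratio, sum
    entropy, sphericity, LDHGLE, cluster prominence, small area emphasis,
    strength) are mapped to a diagnostic likelihood by published polynomial
    likelihood functions; the filter tracks the posterior of the score over
    five half-yearly intervals and classifies each nodule as benign,
    early-stage or advanced-stage cancer from the final posterior mean
    estimate. Includes cubic-spline densification of annual readings, a
    class-consistent synthetic cohort generator built by inverting the
    likelihood polynomials, a deterministic grid-Bayes reference filter, and
    confusion-matrix / MCC / ROC evaluation tools.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
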