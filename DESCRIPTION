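Package: catrace
Title: Calcium Transient Kinetics in Paced Cardiomyocyte Fluorescence Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intracellular Ca2+ transients recorded from
    field-stimulated cardiomyocytes loaded with a fluorescent Ca2+ indicator
    (e.g. Fluo-4). Extracts background-subtracted region-of-interest traces
    from time-lapse image stacks, normalizes them to dF/F0 using a pre-rise
    baseline window, detects paced transients by topographic prominence,
    computes amplitude and rate-of-rise statistics with cell-eligibility
    quality control, fits single-exponential decays, and decomposes the
    caffeine protocol into SERCA2 (systolic minus caffeine decay rate) and
    NCX contributions, fractional SR Ca2+ release, and group-level statistics
    (t tests, ANOVA with Sidak or Tukey post hoc tests, quartile
    stratification with 1.5 IQR outlier removal). Includes a ground-truth
    simulator of paced recordings (traces and image stacks) so that every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
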