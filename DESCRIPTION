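Package: crisprisim
Title: Kinetic Simulation of CRISPRi Repression with Multiple Guide RNA Target Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and integrates ordinary-differential-equation models of
    CRISPR interference (dCas9) transcriptional repression for transiently
    expressed plant promoters carrying multiple guide RNA target sites, either
    heterogeneous (one guide per site) or identical (one guide shared by all
    sites, with lateral scanning between neighbouring sites). Computes fold
    repression of a GFP reporter relative to the unregulated system, fits
    base-expression parameters to calibrated fluorescence (MEFL) time courses
    by least squares in log-parameter space, generates replicate-structured
    synthetic MEFL time-course tables, and runs robustness analyses: one-at-a-
    time parameter perturbation scans, vector-dosage scans, and Monte-Carlo
    cell-to-cell variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
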