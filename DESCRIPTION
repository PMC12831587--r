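Package: qarelax
Title: Deconvolution of Flash-Induced Chlorophyll Fluorescence Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and multicomponent deconvolution of QA- reoxidation
    kinetics measured as the relaxation of flash-induced variable chlorophyll
    fluorescence in cyanobacteria. Decays are modelled as a sum of exponential
    phases (forward electron transfer from QA- to QB and to the plastoquinone
    pool) and a hyperbolic phase (charge recombination with the donor side of
    photosystem II), fitted by bounded multi-start nonlinear least squares;
    the DCMU-poisoned two-component variant is supported. Includes a seeded
    synthetic-trace generator with biological replicate scatter, aggregation
    of replicate fits into mean-and-SD tables with pairwise significance
    marks, and helpers for PAM quantum yields, oxygen-rate fold changes and
    relative qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
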