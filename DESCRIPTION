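Package: txtlsim
Title: Quantitative Modeling of Cell-Free Transcription-Translation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ODE-based kinetic model of gene expression in an all-E. coli
    cell-free transcription-translation (TXTL) system. Three differential
    equations (mRNA, immature and mature reporter protein) are coupled to
    algebraic conservation laws partitioning core RNA polymerase and ribosomes
    between free and engaged pools. The package simulates deGFP expression
    kinetics, computes steady-state mRNA levels and linear-regime protein
    synthesis rates, fits biochemical constants (mRNA lifetime, maturation
    rate, catalytic rate constants) to plate-reader data, runs one-at-a-time
    sensitivity scans, quantifies promoter and UTR strengths from
    rate-versus-plasmid curves, and provides a DNA load calculator predicting
    the plasmid concentration at which translation resources saturate.
    A synthetic-data generator emulates noisy plate-reader measurements with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
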