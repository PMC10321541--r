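Package: tempozoo
Title: Cross-Species Analysis of Segmentation Clock Tempo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for comparative ('stem cell zoo') studies of
    the mammalian segmentation clock. Simulates the HES7 delayed
    negative-feedback oscillator and its linear parameter scaling, estimates
    clock kinetics from luminescence reporter time series (wavelet period,
    RANSAC exponential-decay protein half-life, cross-correlation intron
    delay), relates periods to organismal traits and kinetic parameters by
    linear scaling fits, and profiles cross-species RNA-seq expression against
    the clock period (one-to-one ortholog gluing, GeTMM normalization, exact
    small-n Spearman correlation, tempo gene-set selection). Includes a
    synthetic-data module that emulates the statistical structure of the
    luminometer and count-matrix inputs so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    deSolve
Config/testthat/edition: 3
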