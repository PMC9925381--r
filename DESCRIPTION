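Package: chicdyn
Title: Downstream Analysis of Single-Cell sortChIC Histone Modification Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification, quality control and modelling of single-cell
    histone-modification cut counts from sortChIC experiments. Provides
    genome binning and TSS windows, cell filtering and above-background bin
    calling, a collapsed-Gibbs multinomial topic model with latent-space
    batch correction, Poisson-deviance differential chromatin testing with
    fate-independence classification, ridge-regression inference of
    single-cell transcription factor motif activities, multinomial-mixture
    deconvolution of double-incubated cells, reference-based probabilistic
    cell typing, FACS marker imputation with ternary differentiation
    coordinates, and spline-based chromatin velocity along pseudotime. A
    seeded synthetic-data generator emulates the statistical structure of
    every stage so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    splines,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
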