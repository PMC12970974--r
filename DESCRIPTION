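Package: dispvar
Title: Dispersion Metrics and Differential Variability for Single-Cell Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation benchmark for six dispersion metrics (Gini index,
    variance-to-mean ratio, variance, Shannon entropy, CV, CV^2) on
    single-cell RNA-seq count matrices drawn from Poisson, negative
    binomial, beta-Poisson, Poisson-lognormal, hurdle negative binomial
    and uniform families along fixed-ratio dispersion ladders, together
    with a differential-variability (delta VMR) pipeline for two-condition
    UMI count data: quality control, depth normalization, per-condition
    Fano factors, Wilcoxon differential expression, and rank correlations
    of variability changes with gene characteristics. Includes a
    synthetic-data generator for complete two-condition studies with
    planted variable and differentially expressed genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
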