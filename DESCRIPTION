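Package: pilotpower
Title: Replicate Number and Library Size Evaluation for RNA-Seq
    Differential Expression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates bulk RNA-Seq experimental designs from pilot count
    data. Given a two-condition pilot experiment, the package quantifies how
    the number of biological replicates and the per-sample library size
    drive the number of differentially expressed (DE) genes, their
    stability across repeated subsamples, the statistical power against a
    stringent full-data reference list, and false positive rates, using a
    native negative-binomial exact-test pipeline (TMM normalization,
    conditional-likelihood dispersion estimation, sum-conditioned exact
    test, Benjamini-Hochberg adjustment). It also extracts the ROC-optimal
    FDR threshold per replicate number and fits its relationship to the
    replicate number, simulates pseudo-replicates by multinomial resampling
    of convex combinations of real replicates for meta-analysis style
    DE-count surfaces, and ships a negative-binomial pilot-data simulator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
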