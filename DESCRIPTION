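Package: cnadiff
Title: Paired Array-CGH Copy-Number Analysis and Drug-Resistance Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-channel array-CGH copy-number analysis of paired
    (parental vs. drug-resistant) cell lines: dye and GC-content loess
    normalization of raw channel intensities into log2(Test/Ref) profiles,
    circular binary segmentation with a permutation test, density-peak
    profile centering, derivative-median aberration calling,
    dynamics-scaled differential profiling with gene and cytoband
    annotation, hierarchical clustering of profiles, hypergeometric
    cytoband enrichment, four-parameter logistic dose-response fits with
    IC50 extraction, and resistance-index computation. Includes a
    ground-truth synthetic data generator emulating 180K-probe paired
    hybridizations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
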