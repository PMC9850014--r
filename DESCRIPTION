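Package: invadepop
Title: Demographic and Spatial Population Genomics of Invasive Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the demographic and spatial history of
    recently introduced populations from SNP genotypes. Provides a serial-sampling
    coalescent simulator and a forward-time stepping-stone simulator, a RAD-style
    locus filtering cascade (iterative missingness, minor-allele count, HDplot
    paralog detection, one-SNP-per-locus), population- and individual-level
    diversity statistics with permutation tests, linkage-disequilibrium effective
    population size with allele-frequency (Pcrit) screening, approximate Bayesian
    computation with random forests for bottleneck scenario choice and parameter
    estimation, non-spatial clustering (PCA, K-means BIC scan, DAPC), and spatially
    explicit connectivity analyses (sPCA, Moran eigenvector maps, Mantel
    correlograms with genetic neighbourhood sizing, neighbourhood diversity, and
    directional distance-decay regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    vegan,
    ranger,
    vcfR,
    igraph,
    lmtest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
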