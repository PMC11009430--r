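Package: genrescue
Type: Package
Title: Genetic Monitoring and Genetic Rescue Planning for Small Riverine Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SNP-based genetic monitoring of small, inbred
    riverine fish populations and for planning genetic rescue by
    translocation. Implements genotype quality control for
    reduced-representation SNP panels, individual heterozygosity and
    ordination-based ancestry classification, one-level AMOVA,
    relatedness-based duplicate, sibship and parentage inference,
    single-cohort effective-number-of-breeders estimation by the linkage
    disequilibrium and sibship-frequency methods with life-history
    adjustments, Gompertz growth modelling with length-based cohort
    assignment and inbreeding-depression regressions, sibling-pair
    dispersal inference, and the migrant-number planning calculus. A
    riverscape pedigree simulator with Mendelian gene drop provides ground
    truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    minpack.lm,
    nlme,
    igraph,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
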