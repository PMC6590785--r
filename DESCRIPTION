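Package: tourney
Title: Tournament-Based Marker Screening for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative tournament screening of SNP markers for genome-wide
    selection: markers are partitioned into small regression groups, each
    group is fitted by ordinary least squares, the worst marker of each
    group is eliminated, and survivors are pooled and regrouped until a
    target panel size remains.  The elimination order yields a genome-wide
    marker ranking.  A Park-Casella Bayesian Lasso Gibbs sampler estimates
    marker effects for genomic breeding value prediction, performs
    top-|estimate| and HPD-interval marker selection, and backs k-fold
    cross-validation of predictive ability.  Includes genotype panel I/O
    (dosage/map tables and VCF), the standard sample and marker quality
    control filters (call rate, heterozygosity outliers, MAF, fixed and
    adjacent-redundant markers, MDS coordinates), and a simulation
    framework generating multi-chromosome panels with local linkage
    disequilibrium, planted QTL-effect scenarios, and phenotypes at
    chosen heritabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
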