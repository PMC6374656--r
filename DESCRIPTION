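Package: landgen
Title: Landscape Genetics of Microsatellite Data with Coalescent ABC and
    Ensemble Species Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genetic analysis of multi-population diploid
    microsatellite datasets: GENEPOP input/output and validation, diversity
    and differentiation statistics (heterozygosity, F-statistics, Nei
    distance, UPGMA trees, permutation HWE/LD screens), multivariate
    clustering (PCA, K-means with BIC selection, iterative majority merging,
    DAPC with a-score optimisation), spatially explicit attribution of
    genetic structure (Mantel and partial Mantel tests, spatial PCA with
    Monte Carlo tests, RDA/partial RDA variance partitioning with
    permutation ANOVA), coalescent simulation of microsatellites under
    stepwise mutation with rejection ABC for divergence times, and an
    AUC-weighted ensemble species distribution model (logistic regression
    with BIC averaging, BIOCLIM, Mahalanobis distance, plugin slot)
    projectable onto alternative climate grids. Synthetic-data generators
    with known truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    geosphere,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
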