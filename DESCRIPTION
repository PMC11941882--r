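Package: jarflavor
Title: Pottery-Jar Formulation Effects on Baijiu Flavor Chemistry
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking storage-vessel (pottery jar) formulation
    variables to the flavor chemistry of Maotai-flavored Baijiu during aging.
    Provides readers for the study's jar-parameter, metal-ion and
    flavor-substance tables; K-means clustering of flavor trajectories with a
    size-based representative-selection rule; a consensus key-feature selection
    procedure combining three feature rankers (RReliefF, univariate F-test,
    Boruta) with three tree-ensemble regressors (random forest, gradient
    boosting, AdaBoost.R2) over nested forward subsets, evaluated by test-set
    R-squared, RMSEP and RPD; partial-correlation analysis with time-point
    controls; correlation-network export; and a synthetic-study generator with
    planted ion-to-flavor dependencies for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
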