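Package: hapselect
Title: Multi-Pollutant Bayesian Variable Selection for Case-Control Studies
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating many correlated environmental exposures
    (hazardous air pollutants, HAPs) simultaneously in case-control data.
    Implements control-percentile exposure categorization, Spearman
    correlation binning with representative selection to reduce
    collinearity, hierarchical Bayesian logistic regression with an
    area-level (census tract) random intercept fit by Polya-Gamma Gibbs
    sampling, stochastic search variable selection (SSVS) with a
    spike-and-slab mixture prior and marginal Bayes factors, a two-stage
    final joint model, and a synthetic case-control cohort generator for
    end-to-end testing without access to registry data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
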