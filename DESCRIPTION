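Package: msnmix
Title: Multispecies N-Mixture Models with Trait-Correlated Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of species abundances from
    repeated point counts of a community of species, accounting for imperfect
    detection. Latent site- and species-specific abundances follow Poisson
    distributions whose log-means combine habitat covariates with species
    intercepts that are multivariate normal, correlated through an exponential
    function of morphological-trait dissimilarity (among all species, within
    foraging guilds, or independent). Observed counts are binomial thinnings
    of the latent abundances with logit-linear species detectability. Includes
    a generative simulator, an adaptive Metropolis-within-Gibbs sampler with
    exact discrete updates of the latent abundances, posterior summaries with
    Monte Carlo standard errors, and posterior-predictive loss model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
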