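Package: diallelmm
Title: Bayesian Diallel Mixed Models for Litter Size and Sex Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian analysis of full diallel crossing designs with
    discrete reproductive outcomes. Fits generalized linear mixed models
    with the complete diallel effect decomposition (additive, parental-sex,
    inbred, and symmetric/asymmetric epistatic effects, all under
    sum-to-zero constraints) to weaned litter sizes via an overdispersed
    zero-truncated Poisson likelihood, to variance-stabilized litter sizes
    via a Gaussian likelihood, and to litter sex counts via a binomial
    logit likelihood. Provides dam/sire reparameterization of additive and
    parental-sex effects, diallel variance projections (heritability-like
    partitions of the phenotypic variance of an idealized complete,
    balanced diallel), highest posterior density summaries, pup-scale
    effect translation, a synthetic breeding-record generator for the
    eight Collaborative Cross founder strains, and classical ANOVA and
    exact binomial side analyses of environmental and sex-ratio effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
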