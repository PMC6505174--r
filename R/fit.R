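#' MCMC configuration for diallel fits
#'
#' Bundles the sampler settings shared by all three outcome models. The
#' defaults (3 chains of 50,000 iterations, 10,000 burn-in, thinning 10)
#' are generous for a diallel of a few thousand litters; simulation
#' studies in the package's own tests use shorter, explicitly configured
#' chains. The seed is mandatory: every fit must be reproducible
#' bit-for-bit from its configuration.
#'
#' @param seed integer RNG seed (required). Chain `c` runs under
#'   `seed + c - 1`.
#' @param n_iter total iterations per chain.
#' @param n_burn burn-in iterations discarded per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of independent chains.
#' @param classes random-effect classes to include. Defaults to the full
#'   decomposition; restricting it (e.g. `classes = character(0)` for an
#'   intercept-only model) is mainly useful for calibration checks.
#' @param fixed_var prior variance of the fixed effects (intercept,
#'   parity slope, overall inbred penalty); default 1e3.
#' @param ig_shape,ig_scale shape and scale of the inverse-gamma prior
#'   shared by all variance components; default 0.001 and 0.001.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(seed,
                       n_iter = 50000L, n_burn = 10000L, thin = 10L,
                       n_chains = 3L,
                       classes = c("a", "m", "b", "v", "w", "batch", "order"),
                       fixed_var = 1000, ig_shape = 0.001, ig_scale = 0.001) {
  if (missing(seed)) stop("'seed' must be given explicitly")
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  thin <- as.integer(thin); n_chains <- as.integer(n_chains)
  stopifnot(n_iter > n_burn, n_burn >= 0, thin >= 1, n_chains >= 1,
            fixed_var > 0, ig_shape > 0, ig_scale > 0)
  all_classes <- c("a", "m", "b", "v", "w", "batch", "order")
  classes <- as.character(classes)
  if (length(setdiff(classes, all_classes)))
    stop("unknown class(es): ", paste(setdiff(classes, all_classes), collapse = ", "))
  structure(list(seed = as.integer(seed), n_iter = n_iter, n_burn = n_burn,
                 thin = thin, n_chains = n_chains, classes = classes,
                 fixed_var = fixed_var, ig_shape = ig_shape,
                 ig_scale = ig_scale),
            class = "fit_config")
}

param_names <- function(strains) {
  pl <- strain_pairs(strains)$label
  c("mu", "alpha", "beta_inbred",
    paste0("a.", strains), paste0("m.", strains), paste0("b.", strains),
    paste0("v.", pl), paste0("w.", pl),
    paste0("order.", 1:12), paste0("batch.", 1:48),
    "sigma2",
    paste0("tau2.", c("a", "m", "b", "v", "w", "batch", "order")))
}

run_chains <- function(model_code, design, response, ntrials, config) {
  inc <- c("a", "m", "b", "v", "w", "batch", "order") %in% config$classes
  draws <- vector("list", config$n_chains)
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    draws[[chain]] <- diallel_gibbs_cpp(
      model = model_code,
      y = response,
      ntrials = ntrials,
      jdx = design$j - 1L, kdx = design$k - 1L,
      pairdx = ifelse(is.na(design$pair), -1L, design$pair - 1L),
      asign = design$asym_sign,
      batchdx = design$batch - 1L,
      orddx = design$parity - 1L,
      n_iter = config$n_iter, n_burn = config$n_burn, thin = config$thin,
      fixed_var = config$fixed_var, ig_shape = config$ig_shape,
      ig_scale = config$ig_scale,
      include = inc)
  }
  out <- do.call(rbind, draws)
  colnames(out) <- param_names(design$strains)
  list(draws = out,
       chain = rep(seq_len(config$n_chains), each = nrow(draws[[1L]])))
}

new_diallel_fit <- function(run, model, config, design) {
  structure(list(draws = run$draws, chain = run$chain, model = model,
                 config = config, strains = design$strains,
                 n_obs = design$n),
            class = "diallel_fit")
}

#' Fit the zero-truncated Poisson diallel model to litter sizes
#'
#' Samples the posterior of the overdispersed zero-truncated Poisson
#' GLMM: weaned litter size `y_i ~ ZTPois(exp(l_i))` with latent
#' `l_i = eta_i + eps_i`, `eps_i ~ N(0, sigma2)` providing litter-level
#' overdispersion, and the linear predictor `eta_i` composed of an
#' intercept, parity and batch effects, and the full diallel
#' decomposition of the parental strain combination (additive,
#' parental-sex, inbred, and symmetric/asymmetric epistatic effects).
#' Sum-to-zero constraints on each strain/pair effect class hold exactly
#' at every retained draw. All Gaussian layers are updated by conjugate
#' block Gibbs steps; each latent `l_i` is updated by slice sampling
#' against the ZTP likelihood, which needs no step-size tuning.
#'
#' @param records validated litter records (see [validate_records()]);
#'   all litter sizes must be at least 1.
#' @param strains a [diallel_strains()] strain set.
#' @param config a [fit_config()].
#' @return An object of class `"diallel_fit"`: a matrix of posterior
#'   draws (one scalar parameter per column, chains stacked), chain ids,
#'   the model tag, the configuration, and the strain set.
#' @seealso [fit_gaussian_diallel()], [fit_binomial_diallel()],
#'   [effect_summary()], [compute_varp()]
#' @export
fit_ztp_diallel <- function(records, strains = diallel_strains(),
                            config = fit_config(seed = 1)) {
  design <- build_design(records, strains)
  if (any(design$y < 1 | design$y != floor(design$y)))
    stop("litter sizes must be positive integers for the zero-truncated model")
  run <- run_chains(1L, design, design$y, numeric(design$n), config)
  new_diallel_fit(run, "ztp", config, design)
}

#' Fit the Gaussian diallel model to transformed litter sizes
#'
#' Fits the same diallel hierarchy as [fit_ztp_diallel()] but with a
#' Gaussian likelihood on a variance-stabilizing transformation of
#' litter size (the square root by default), corresponding to the linear
#' mixed model approximation of the count model. All updates are fully
#' conjugate.
#'
#' @inheritParams fit_ztp_diallel
#' @param transform `"sqrt"` (default) or `"identity"` (fit the response
#'   as supplied).
#' @return A `"diallel_fit"` with model tag `"gaussian_sqrt"` or
#'   `"gaussian_identity"`.
#' @export
fit_gaussian_diallel <- function(records, strains = diallel_strains(),
                                 config = fit_config(seed = 1),
                                 transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  design <- build_design(records, strains)
  if (transform == "sqrt" && any(design$y < 1))
    stop("litter sizes must be at least 1")
  resp <- if (transform == "sqrt") sqrt(design$y) else design$y
  run <- run_chains(0L, design, resp, numeric(design$n), config)
  new_diallel_fit(run, paste0("gaussian_", transform), config, design)
}

#' Fit the binomial diallel model to litter sex counts
#'
#' Models the number of male pups per litter as
#' `males_i ~ Binom(n_i, expit(l_i))`, with the latent logit male
#' proportion `l_i` following the identical diallel hierarchy
#' (including litter-level overdispersion) as the litter-size models.
#' Latent values are slice-sampled against the binomial likelihood.
#'
#' @inheritParams fit_ztp_diallel
#' @param records validated records with `n_male` present and
#'   `0 <= n_male <= litter_size`.
#' @return A `"diallel_fit"` with model tag `"binomial"`.
#' @export
fit_binomial_diallel <- function(records, strains = diallel_strains(),
                                 config = fit_config(seed = 1)) {
  design <- build_design(records, strains)
  if (anyNA(design$n_male))
    stop("all records need male counts for the sex-ratio model")
  if (any(design$n_male < 0 | design$n_male > design$y))
    stop("male counts must satisfy 0 <= n_male <= litter_size")
  run <- run_chains(2L, design, design$n_male, design$y, config)
  new_diallel_fit(run, "binomial", config, design)
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat("Diallel GLMM fit (", x$model, ")\n", sep = "")
  cat("  observations: ", x$n_obs, "\n", sep = "")
  cat("  chains: ", x$config$n_chains, ", retained draws: ",
      nrow(x$draws), " (", x$config$n_iter, " iter, ",
      x$config$n_burn, " burn-in, thin ", x$config$thin, ")\n", sep = "")
  cat("  seed: ", x$config$seed, "\n", sep = "")
  cat("  strains: ", paste(x$strains, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Draw a sum-to-zero constrained Gaussian vector
#'
#' Samples from a multivariate normal `N(mean, precision^-1)` restricted
#' to the hyperplane where coordinates sum to zero, by drawing from the
#' unconstrained Gaussian and conditioning on the sum (a rank-one update
#' using the covariance). This is the update used for every strain and
#' strain-pair effect class in the samplers; under an exchangeable prior
#' with variance `tau2` the marginal variance of each coordinate is
#' `tau2 * (K - 1) / K`.
#'
#' @param mean length-`K` unconstrained mean (`K >= 2`).
#' @param precision `K x K` symmetric positive-definite precision
#'   matrix, or a length-`K` vector of diagonal precisions.
#' @return A length-`K` numeric vector whose sum is zero (to numerical
#'   precision).
#' @export
draw_sum_to_zero <- function(mean, precision) {
  K <- length(mean)
  if (K < 2) stop("sum-to-zero constraint needs at least 2 coordinates")
  if (is.matrix(precision)) {
    stopifnot(nrow(precision) == K, ncol(precision) == K)
    U <- chol(precision)
    z <- mean + backsolve(U, stats::rnorm(K))
    s <- backsolve(U, backsolve(U, rep(1, K), transpose = TRUE))
  } else {
    stopifnot(length(precision) == K, all(precision > 0))
    z <- mean + stats::rnorm(K) / sqrt(precision)
    s <- 1 / precision
  }
  z - s * (sum(z) / sum(s))
}

#' Convergence diagnostics for a diallel fit
#'
#' Computes the split-chain potential scale reduction factor (split
#' PSRF) and an effective sample size per scalar parameter. Each chain
#' is split in half before comparing within- to between-chain variance;
#' ESS uses Geyer's initial positive sequence of paired autocorrelations
#' summed over chains. Parameters with split PSRF above 1.05 are
#' flagged. With a single chain only ESS is available and a warning is
#' issued.
#'
#' @param fit a `"diallel_fit"`, or a numeric matrix of draws.
#' @param chain integer chain ids per row (taken from the fit when a fit
#'   is supplied).
#' @return A data frame with columns `parameter`, `psrf`, `ess`,
#'   `flagged`.
#' @export
convergence_diagnostics <- function(fit, chain = NULL) {
  if (inherits(fit, "diallel_fit")) {
    draws <- fit$draws
    chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) chain <- rep(1L, nrow(draws))
  }
  chains <- split(seq_len(nrow(draws)), chain)
  single <- length(chains) < 2L
  if (single)
    warning("only one chain: PSRF unavailable, reporting ESS only")

  psrf_one <- function(x_by_chain) {
    # split each chain in half -> 2C sequences of equal length
    halves <- unlist(lapply(x_by_chain, function(x) {
      nh <- floor(length(x) / 2)
      list(x[seq_len(nh)], x[nh + seq_len(nh)])
    }), recursive = FALSE)
    m <- length(halves); nl <- length(halves[[1L]])
    if (nl < 2L) return(NA_real_)
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- nl * stats::var(means)
    if (W <= .Machine$double.eps) return(1)
    sqrt(((nl - 1) / nl * W + B / nl) / W)
  }

  ess_one <- function(x_by_chain) {
    tot <- 0
    for (x in x_by_chain) {
      nx <- length(x)
      if (stats::var(x) <= .Machine$double.eps) { tot <- tot + nx; next }
      lag_max <- min(nx - 1L, 2000L)
      rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                                   demean = TRUE)$acf)[-1L]
      # Geyer: sum paired autocorrelations while positive, enforcing the
      # initial monotone sequence to damp noise in the tail
      s <- 0
      i <- 1L
      prev <- Inf
      while (i < length(rho)) {
        p <- rho[i] + rho[i + 1L]
        if (p < 0) break
        p <- min(p, prev)
        prev <- p
        s <- s + p
        i <- i + 2L
      }
      tot <- tot + nx / (1 + 2 * s)
    }
    tot
  }

  res <- data.frame(
    parameter = colnames(draws),
    psrf = NA_real_, ess = NA_real_,
    stringsAsFactors = FALSE
  )
  for (p in seq_len(ncol(draws))) {
    xs <- lapply(chains, function(idx) draws[idx, p])
    if (!single) res$psrf[p] <- psrf_one(xs)
    res$ess[p] <- ess_one(xs)
  }
  res$flagged <- !is.na(res$psrf) & res$psrf > 1.05
  res
}
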