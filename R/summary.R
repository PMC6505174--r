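#' Highest posterior density interval
#'
#' Computes the shortest contiguous interval containing at least
#' `ceiling(prob * n)` of the sorted samples — the standard empirical
#' HPD interval for a unimodal marginal posterior.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param prob coverage probability in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L) stop("need at least 100 samples for an HPD interval")
  if (!(prob > 0 && prob < 1)) stop("'prob' must be in (0, 1)")
  hpd_core(samples, prob)
}

# unchecked kernel, also used internally on short draw vectors
hpd_core <- function(samples, prob) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(prob * n)
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

summarize_draws <- function(mat) {
  h50 <- apply(mat, 2, hpd_core, prob = 0.50)
  h95 <- apply(mat, 2, hpd_core, prob = 0.95)
  data.frame(
    name = colnames(mat),
    mean = colMeans(mat),
    median = apply(mat, 2, stats::median),
    hpd50_lo = h50[1L, ], hpd50_hi = h50[2L, ],
    hpd95_lo = h95[1L, ], hpd95_hi = h95[2L, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Posterior effect summary table
#'
#' Summarizes every scalar parameter of a fit (or a chosen subset of
#' effect classes) with posterior mean, median, and 50%/95% HPD
#' intervals, mirroring the usual diallel effect-plot content.
#'
#' @param fit a `"diallel_fit"`.
#' @param classes optional character vector of parameter-name prefixes
#'   to keep (e.g. `c("a", "m", "mu")`); by default everything.
#' @return A data frame with columns `name`, `mean`, `median`,
#'   `hpd50_lo`, `hpd50_hi`, `hpd95_lo`, `hpd95_hi`.
#' @export
effect_summary <- function(fit, classes = NULL) {
  stopifnot(inherits(fit, "diallel_fit"))
  mat <- fit$draws
  if (!is.null(classes)) {
    pref <- sub("\\..*$", "", colnames(mat))
    mat <- mat[, pref %in% classes, drop = FALSE]
    if (ncol(mat) == 0L) stop("no parameters match the requested classes")
  }
  summarize_draws(mat)
}

#' Reparameterize additive and parental-sex effects as dam/sire effects
#'
#' Maps each posterior draw of the additive (`a`) and parental-sex (`m`)
#' effects to directional parental effects: `dam_j = a_j + m_j` is the
#' effect of strain j entering through the mother, `sire_j = a_j - m_j`
#' through the father. The map is an exact per-draw linear
#' post-processing step; the underlying model and all other effect
#' classes are untouched, and the inverse map (`a = (dam + sire)/2`,
#' `m = (dam - sire)/2`) recovers the original draws exactly. Both
#' derived classes inherit the sum-to-zero property.
#'
#' @param fit a `"diallel_fit"` containing `a` and `m` draws.
#' @return A list with matrices `dam` and `sire` (draws x 8 strains).
#' @export
reparameterize_dam_sire <- function(fit) {
  stopifnot(inherits(fit, "diallel_fit"))
  a <- fit$draws[, paste0("a.", fit$strains), drop = FALSE]
  m <- fit$draws[, paste0("m.", fit$strains), drop = FALSE]
  dam <- a + m
  sire <- a - m
  colnames(dam) <- paste0("dam.", fit$strains)
  colnames(sire) <- paste0("sire.", fit$strains)
  list(dam = dam, sire = sire)
}

# Per-draw linear predictor for all 64 cells at reference covariates:
# parity and batch at their across-level means. The batch mean is kept in
# the reference because only mu + mean(batch) is identified: the intercept
# and the (uncentered) batch effects can drift against each other along a
# prior-limited ridge.
cell_eta_draws <- function(fit) {
  strains <- fit$strains
  d <- fit$draws
  maps <- cell_maps(strains)
  ord_ref <- rowMeans(d[, paste0("order.", 1:12), drop = FALSE])
  bat_ref <- rowMeans(d[, paste0("batch.", 1:48), drop = FALSE])
  eta <- d[, "mu"] + ord_ref + bat_ref +
    d[, paste0("a.", strains), drop = FALSE] %*% t(maps$A) +
    d[, paste0("m.", strains), drop = FALSE] %*% t(maps$M) +
    outer(d[, "beta_inbred"], maps$inb) +
    d[, paste0("b.", strains), drop = FALSE] %*% t(maps$B) +
    d[, grep("^v\\.", colnames(d)), drop = FALSE] %*% t(maps$V) +
    d[, grep("^w\\.", colnames(d)), drop = FALSE] %*% t(maps$W)
  eta
}

#' Posterior expected litter size for every cross
#'
#' Computes the posterior expected weaned litter size of each of the 64
#' dam x sire cells of the diallel at reference covariates (parity and
#' batch effects at their across-level means). For the
#' zero-truncated Poisson model the latent overdispersion is integrated
#' through the lognormal mean factor before truncation:
#' `E[y] = ztp_mean(exp(eta + sigma2/2))`. For the Gaussian square-root
#' model the expectation on the count scale is `eta^2 + sigma2`.
#' Averages over draws.
#'
#' @param fit a `"diallel_fit"` from [fit_ztp_diallel()] or
#'   [fit_gaussian_diallel()].
#' @param strains strain set (defaults to the fit's).
#' @return An 8 x 8 matrix (rows = dam strain, columns = sire strain) of
#'   posterior mean expected litter sizes.
#' @export
expected_cell_means <- function(fit, strains = fit$strains) {
  stopifnot(inherits(fit, "diallel_fit"))
  if (fit$model == "binomial")
    stop("cell means on the count scale are not defined for the binomial model")
  eta <- cell_eta_draws(fit)
  s2 <- fit$draws[, "sigma2"]
  if (fit$model == "ztp") {
    vals <- ztp_mean(exp(eta + s2 / 2))
  } else if (fit$model == "gaussian_sqrt") {
    vals <- eta^2 + s2
  } else {
    vals <- eta
  }
  out <- matrix(colMeans(vals), 8, 8, byrow = TRUE,
                dimnames = list(dam = strains, sire = strains))
  out
}

#' Pup-scale dam and sire effects
#'
#' Translates latent-scale dam/sire effects into interpretable
#' quantities: the fold change `exp(effect)` of the expected litter
#' size, and the change in expected pups relative to a reference cross
#' with that effect set to zero (other terms at reference: intercept,
#' parity at its across-level mean, overdispersion integrated via
#' `exp(sigma2/2)`, and zero-truncation applied on both sides of the
#' comparison).
#'
#' @param fit a `"diallel_fit"` from [fit_ztp_diallel()].
#' @param which `"dam"` (default) or `"sire"`.
#' @return A data frame per strain with posterior mean/median and 95%
#'   HPD of the fold change and the pup-count change.
#' @export
pup_scale_effects <- function(fit, which = c("dam", "sire")) {
  stopifnot(inherits(fit, "diallel_fit"))
  if (fit$model != "ztp")
    stop("pup-scale effects are defined for the zero-truncated Poisson fit")
  which <- match.arg(which)
  eff <- reparameterize_dam_sire(fit)[[which]]
  d <- fit$draws
  ord_ref <- rowMeans(d[, paste0("order.", 1:12), drop = FALSE])
  bat_ref <- rowMeans(d[, paste0("batch.", 1:48), drop = FALSE])
  base_log <- d[, "mu"] + ord_ref + bat_ref + d[, "sigma2"] / 2
  base <- ztp_mean(exp(base_log))              # per-draw reference expectation
  res <- lapply(seq_along(fit$strains), function(s) {
    fold <- exp(eff[, s])
    pup <- ztp_mean(exp(base_log + eff[, s])) - base
    f95 <- hpd_core(fold, 0.95); p95 <- hpd_core(pup, 0.95)
    data.frame(strain = fit$strains[s], role = which,
               fold_mean = mean(fold), fold_median = stats::median(fold),
               fold_hpd95_lo = f95[1L], fold_hpd95_hi = f95[2L],
               pup_mean = mean(pup), pup_median = stats::median(pup),
               pup_hpd95_lo = p95[1L], pup_hpd95_hi = p95[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
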