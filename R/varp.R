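# Linear maps from effect vectors to the 64 diallel cells (dam j, sire k),
# cells enumerated row-major: cell = (j-1)*8 + k. The idealized diallel is
# complete and balanced: all 64 cells, uniform weight, including cells that
# are biologically inviable in the real breeding program.
cell_maps <- function(strains = diallel_strains()) {
  grid <- expand.grid(k = 1:8, j = 1:8)[, c("j", "k")]  # row-major in j
  nc <- 64L
  A <- matrix(0, nc, 8)   # additive: a_j + a_k
  M <- matrix(0, nc, 8)   # parental sex: m_j - m_k
  B <- matrix(0, nc, 8)   # strain inbred: I{j=k} b_j
  V <- matrix(0, nc, 28)  # symmetric epistasis
  W <- matrix(0, nc, 28)  # asymmetric epistasis, sign S{j<k}
  inb <- numeric(nc)      # overall inbred indicator
  for (i in seq_len(nc)) {
    j <- grid$j[i]; k <- grid$k[i]
    A[i, j] <- A[i, j] + 1; A[i, k] <- A[i, k] + 1
    if (j == k) {
      inb[i] <- 1
      B[i, j] <- 1
    } else {
      M[i, j] <- 1; M[i, k] <- -1
      p <- pair_index(j, k)
      V[i, p] <- 1
      W[i, p] <- if (j < k) 0.5 else -0.5
    }
  }
  list(A = A, M = M, B = B, V = V, W = W, inb = inb, grid = grid)
}

#' Per-class cell contribution matrices for one effect state
#'
#' Expands a single set of diallel effects into the 8 x 8 matrices of
#' latent-scale contributions each effect class makes to each dam x sire
#' cell of a complete, balanced diallel: additive `a_j + a_k`,
#' parental sex `m_j - m_k`, overall inbred `I{j=k} beta_inbred`,
#' strain inbred `I{j=k} b_j`, symmetric epistasis `I{j!=k} v_{jk}`, and
#' asymmetric epistasis `I{j!=k} S{j<k} w_{jk}`. All 64 cells are
#' populated, including biologically inviable crosses: the variance
#' projection is a projection onto an idealized design, not a prediction
#' for feasible matings.
#'
#' @param state an effect state: a list with numeric elements
#'   `beta_inbred`, `a` (8), `m` (8), `b` (8), `v` (28), `w` (28).
#' @param strains a [diallel_strains()] strain set.
#' @return A named list of six 8 x 8 matrices (rows = dam, cols = sire).
#' @export
class_contributions <- function(state, strains = diallel_strains()) {
  maps <- cell_maps(strains)
  as_mat <- function(x) matrix(x, 8, 8, byrow = TRUE,
                               dimnames = list(dam = strains, sire = strains))
  list(
    additive = as_mat(maps$A %*% state$a),
    parental_sex = as_mat(maps$M %*% state$m),
    inbred_overall = as_mat(maps$inb * state$beta_inbred),
    inbred_strain = as_mat(maps$B %*% state$b),
    epistatic_symmetric = as_mat(maps$V %*% state$v),
    epistatic_asymmetric = as_mat(maps$W %*% state$w)
  )
}

popvar <- function(x) mean((x - mean(x))^2)

# per-draw class variances and fractions from a fit's draw matrix
varp_fractions <- function(fit, include = c("batch", "order"),
                           dam_sire = FALSE) {
  d <- fit$draws
  strains <- fit$strains
  maps <- cell_maps(strains)
  rowpopvar <- function(m) rowMeans(m^2) - rowMeans(m)^2

  a <- d[, paste0("a.", strains), drop = FALSE]
  m <- d[, paste0("m.", strains), drop = FALSE]
  if (dam_sire) {
    # dam_j is a row effect, sire_k a column effect of the idealized diallel
    dam <- a + m; sire <- a - m
    var_dam <- rowpopvar(dam)        # uniform over cells = over strains
    var_sire <- rowpopvar(sire)
  } else {
    var_add <- rowpopvar(a %*% t(maps$A))
    var_psx <- rowpopvar(m %*% t(maps$M))
  }
  var_inbo <- popvar(maps$inb) * d[, "beta_inbred"]^2
  var_inbs <- rowpopvar(d[, paste0("b.", strains), drop = FALSE] %*% t(maps$B))
  var_epiv <- rowpopvar(d[, grep("^v\\.", colnames(d)), drop = FALSE] %*% t(maps$V))
  var_epiw <- rowpopvar(d[, grep("^w\\.", colnames(d)), drop = FALSE] %*% t(maps$W))

  cls <- if (dam_sire) {
    cbind(dam_strain = var_dam, sire_strain = var_sire)
  } else {
    cbind(additive = var_add, parental_sex = var_psx)
  }
  cls <- cbind(cls,
               inbred_overall = var_inbo, inbred_strain = var_inbs,
               epistatic_symmetric = var_epiv, epistatic_asymmetric = var_epiw)
  n_diallel <- ncol(cls)
  if ("batch" %in% include)
    cls <- cbind(cls, batch = rowpopvar(d[, paste0("batch.", 1:48), drop = FALSE]))
  if ("order" %in% include)
    cls <- cbind(cls, order = rowpopvar(d[, paste0("order.", 1:12), drop = FALSE]))
  denom <- rowSums(cls) + d[, "sigma2"]
  frac <- cls / denom
  frac <- cbind(frac, residual = d[, "sigma2"] / denom)
  frac <- cbind(frac, total_explained = rowSums(frac[, seq_len(n_diallel),
                                                     drop = FALSE]))
  frac
}

#' Diallel variance projections
#'
#' Computes, for every posterior draw, the heritability-like partition
#' of the latent-scale phenotypic variance of an idealized complete,
#' balanced future diallel. Each diallel effect class contributes the
#' population variance of its 64 cell contributions (see
#' [class_contributions()]); the batch class contributes the population
#' variance of the 48 batch effects, and the parity class the
#' population variance of the 12 total parity effects (slope plus
#' deviations), so fixed and random parts are both represented. The
#' denominator is the sum of all class variances plus the residual
#' (overdispersion) variance, so per draw the fractions and the
#' residual fraction sum to exactly 1. Fractions are summarized over
#' draws with posterior mean, median, and 95% HPD; `total_explained` is
#' the per-draw sum of the six diallel class fractions (excluding batch,
#' parity, and residual).
#'
#' Because the model is linear on the latent (log, square-root, or
#' logit) scale only, the projection is computed there; no data-scale
#' variance decomposition is attempted.
#'
#' @param fit a `"diallel_fit"` from [fit_ztp_diallel()] or
#'   [fit_gaussian_diallel()] (the binomial fit is accepted too; its
#'   projection lives on the logit scale).
#' @param include which non-diallel structured classes enter the
#'   denominator (default both `"batch"` and `"order"`).
#' @return An object of class `"varp_summary"`: a data frame (`summary`)
#'   of per-class posterior mean/median/HPD of the variance fractions,
#'   with the per-draw fraction matrix in `fractions`.
#' @export
compute_varp <- function(fit, include = c("batch", "order")) {
  stopifnot(inherits(fit, "diallel_fit"))
  needed <- c("a", "m", "b", "v", "w")
  missing_cls <- setdiff(needed, fit$config$classes)
  if (length(missing_cls))
    stop("fit lacks required effect class(es): ",
         paste(missing_cls, collapse = ", "))
  frac <- varp_fractions(fit, include = include, dam_sire = FALSE)
  new_varp_summary(frac, fit$model)
}

#' @rdname compute_varp
#' @details `varp_dam_sire()` replaces the additive and parental-sex
#'   classes with the reparameterized `dam_strain` and `sire_strain`
#'   classes (row and column variances of the idealized diallel under
#'   `dam_j = a_j + m_j`, `sire_j = a_j - m_j`); per draw the two new
#'   fractions sum exactly to the two they replace, and all other
#'   classes are unchanged.
#' @export
varp_dam_sire <- function(fit, include = c("batch", "order")) {
  stopifnot(inherits(fit, "diallel_fit"))
  needed <- c("a", "m", "b", "v", "w")
  missing_cls <- setdiff(needed, fit$config$classes)
  if (length(missing_cls))
    stop("fit lacks required effect class(es): ",
         paste(missing_cls, collapse = ", "))
  frac <- varp_fractions(fit, include = include, dam_sire = TRUE)
  new_varp_summary(frac, fit$model)
}

new_varp_summary <- function(frac, model) {
  s <- summarize_draws(frac)
  names(s)[names(s) == "name"] <- "class"
  structure(list(summary = s, fractions = frac, model = model),
            class = "varp_summary")
}

#' @export
print.varp_summary <- function(x, ...) {
  cat("Diallel variance projection (", x$model, " fit), fractions of\n",
      "latent-scale variance of an idealized complete balanced diallel:\n",
      sep = "")
  s <- x$summary
  out <- data.frame(class = s$class,
                    mean_pct = round(100 * s$mean, 2),
                    median_pct = round(100 * s$median, 2),
                    hpd95 = sprintf("[%.2f, %.2f]", 100 * s$hpd95_lo,
                                    100 * s$hpd95_hi))
  print(out, row.names = FALSE)
  invisible(x)
}
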