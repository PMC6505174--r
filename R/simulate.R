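# Target latent-scale variance fractions (percent of the idealized-diallel
# variance) for the default generative truth. Components reflect a large
# CC-founder breeding program: moderate additive and maternal (parental-sex)
# heritability, a small inbred penalty, modest epistasis, and a large
# unexplained/overdispersion share.
.default_fracs <- c(additive = 9.18, parental_sex = 5.77,
                    inbred_overall = 1.43, inbred_strain = 0.60,
                    epistatic_symmetric = 2.04, epistatic_asymmetric = 1.36,
                    batch = 2.00, order = 1.00) / 100

# Dam-strain effects on the latent log scale (sum to zero): classical
# strains B6 and NOD raise expected litter size by roughly 1.3-fold; the
# wild-derived strains CAST, PWK, and especially WSB lower it.
.default_dam <- c(AJ = 0.0100, B6 = 0.2655, `129S1` = 0.0256, NOD = 0.2835,
                  NZO = 0.0800, CAST = -0.1802, PWK = -0.1606, WSB = -0.3238)

# Sire-strain pattern (direction only; rescaled during calibration):
# NOD and NZO sires mildly productive, CAST sires mildly unproductive.
.default_sire_shape <- c(AJ = -0.02, B6 = 0.01, `129S1` = -0.04, NOD = 0.09,
                         NZO = 0.07, CAST = -0.10, PWK = -0.01, WSB = 0.00)

center <- function(x) x - mean(x)

#' Default generative truth for a CC-founder litter-size diallel
#'
#' Builds the reference simulation scenario used throughout the
#' package's tests: an 8 x 8 diallel of the Collaborative Cross founder
#' strains with 62 viable crosses (NZO dams crossed to CAST or PWK sires
#' are excluded as unproductive), a diagonal-heavy design of 4,448
#' litters, an overall latent intercept of `log(5.46)` expected pups,
#' and a full set of diallel effects calibrated so that each effect
#' class accounts for a fixed fraction of the latent-scale variance of
#' the idealized complete diallel (additive 9.18%, parental sex 5.77%,
#' overall inbred 1.43%, strain inbred 0.6%, symmetric epistasis 2.04%,
#' asymmetric epistasis 1.36%, batch 2%, parity 1%, the remainder
#' litter-level overdispersion). The dam-strain effects follow the
#' classical-versus-wild-derived pattern (B6 and NOD dams add roughly
#' 1.7 pups, WSB dams remove roughly 1.5) and the additive and
#' parental-sex effects are derived from the dam/sire decomposition, so
#' the dam-strain class carries 13.15% of latent variance against 1.80%
#' for the sire-strain class. The asymmetric epistatic pattern includes
#' a notable negative PWK-dam-by-NOD-sire deviation. The sex-ratio truth
#' is null: logit male proportion `qlogis(0.4979)` with no strain
#' effects and slight litter-level overdispersion.
#'
#' @param seed integer seed controlling the haphazard parts of the truth
#'   (strain-inbred, epistatic, batch, and parity-deviation patterns);
#'   the calibrated variance fractions are identical for every seed.
#' @return A list of class `"sim_truth"`: `state` (the full effect
#'   state), `sexratio` (effect state for the binomial model), `design`
#'   (data frame of per-cross litter counts), `strains`, and
#'   `target_fracs`.
#' @export
default_truth <- function(seed = 1) {
  strains <- diallel_strains()
  fr <- .default_fracs
  set.seed(as.integer(seed))

  dam <- .default_dam
  D <- popvar(dam) / 0.1315        # latent-scale total variance implied by
                                   # the dam effects carrying 13.15% of it
  # sire effects: popvar 0.0180*D, cov with dam fixed so that the additive
  # class carries fr["additive"] and parental sex fr["parental_sex"]
  # (dam+sire class variances = additive+parental-sex class variances)
  v_sire <- (fr[["additive"]] + fr[["parental_sex"]] - 0.1315) * D
  c_ds <- (fr[["additive"]] - fr[["parental_sex"]]) / 2 * D
  e <- center(.default_sire_shape)
  e <- e - dam * sum(e * dam) / sum(dam^2)       # orthogonalize against dam
  e <- e / sqrt(popvar(e))
  alpha_ds <- c_ds / popvar(dam)                 # cov/var regression weight
  sire <- alpha_ds * dam + sqrt(max(v_sire - alpha_ds^2 * popvar(dam), 0)) * e
  a <- (dam + sire) / 2
  m <- (dam - sire) / 2

  # overall inbred penalty: cell variance (1/8)(7/8) beta^2 = fr * D
  beta_inbred <- -sqrt(fr[["inbred_overall"]] * D / (7 / 64))

  # strain-specific inbred deviations: cell variance sum(b^2)/64 = fr * D
  b <- center(stats::rnorm(8))
  b <- b * sqrt(fr[["inbred_strain"]] * D * 64 / sum(b^2))

  # symmetric epistasis: cell variance 2*sum(v^2)/64 = fr * D
  v <- center(stats::rnorm(28))
  v <- v * sqrt(fr[["epistatic_symmetric"]] * D * 32 / sum(v^2))

  # asymmetric epistasis: cell variance sum(w^2)/128 = fr * D; seed a strong
  # positive NOD:PWK entry so the PWK-dam x NOD-sire cell deviates downward
  w <- stats::rnorm(28, sd = 0.5)
  w[pair_index(4L, 7L)] <- 2.0
  w <- center(w)
  w <- w * sqrt(fr[["epistatic_asymmetric"]] * D * 128 / sum(w^2))

  # batch effects: population variance fr * D over the 48 levels
  batch <- center(stats::rnorm(48))
  batch <- batch * sqrt(fr[["batch"]] * D / popvar(batch))

  # parity: declining slope with a first-litter deficit; total parity
  # effects (r*alpha + deviation) rescaled to carry fr * D
  alpha <- -0.012
  dev <- c(-0.09, stats::rnorm(11, sd = 0.02))
  tot <- (1:12) * alpha + dev
  g <- sqrt(fr[["order"]] * D / popvar(tot))
  alpha <- alpha * g
  ord <- tot * g

  sigma2 <- D * (1 - sum(fr))

  state <- list(
    mu = log(5.46), alpha = alpha, beta_inbred = beta_inbred,
    a = stats::setNames(as.numeric(a), strains),
    m = stats::setNames(as.numeric(m), strains),
    b = stats::setNames(as.numeric(b), strains),
    v = stats::setNames(as.numeric(v), strain_pairs(strains)$label),
    w = stats::setNames(as.numeric(w), strain_pairs(strains)$label),
    order = ord, batch = batch, sigma2 = sigma2,
    tau2 = list(a = popvar(a), m = popvar(m), b = popvar(b),
                v = popvar(v), w = popvar(w),
                batch = popvar(batch), order = popvar(ord - (1:12) * alpha))
  )

  sexratio <- list(
    mu = stats::qlogis(0.4979), alpha = 0, beta_inbred = 0,
    a = stats::setNames(numeric(8), strains),
    m = stats::setNames(numeric(8), strains),
    b = stats::setNames(numeric(8), strains),
    v = stats::setNames(numeric(28), strain_pairs(strains)$label),
    w = stats::setNames(numeric(28), strain_pairs(strains)$label),
    order = numeric(12), batch = numeric(48), sigma2 = 0.01,
    tau2 = list(a = 0, m = 0, b = 0, v = 0, w = 0, batch = 0, order = 0)
  )

  structure(list(state = state, sexratio = sexratio,
                 design = default_design(strains), strains = strains,
                 target_fracs = fr, latent_var = D),
            class = "sim_truth")
}

# Diagonal-heavy design: inbred cells carry ~5x the litters of F1 cells,
# NZO x CAST and NZO x PWK (dam x sire) are inviable; 4,448 litters total.
default_design <- function(strains = diallel_strains()) {
  grid <- expand.grid(sire = strains, dam = strains,
                      stringsAsFactors = FALSE)[, c("dam", "sire")]
  inviable <- (grid$dam == "NZO" & grid$sire %in% c("CAST", "PWK"))
  grid <- grid[!inviable, , drop = FALSE]
  n <- ifelse(grid$dam == grid$sire, 238L, 47L)
  extra <- which(grid$dam != grid$sire)[1:6]
  n[extra] <- n[extra] + 1L
  grid$n_litters <- n
  rownames(grid) <- NULL
  grid
}

state_eta <- function(state, j, k, parity, batch, strains) {
  pair <- ifelse(j == k, NA_integer_, pair_index(j, k))
  asign <- ifelse(j == k, 0, ifelse(j < k, 0.5, -0.5))
  eta <- state$mu + state$order[parity] + state$batch[batch] +
    state$a[j] + state$a[k]
  off <- j != k
  eta[off] <- eta[off] + state$m[j[off]] - state$m[k[off]] +
    state$v[pair[off]] + asign[off] * state$w[pair[off]]
  eta[!off] <- eta[!off] + state$beta_inbred + state$b[j[!off]]
  unname(eta)
}

#' Simulate weaned-litter records from a generative truth
#'
#' Runs the zero-truncated Poisson diallel model generatively: litters
#' are laid out per the truth's cross design and grouped into mating
#' pairs whose litter counts follow a truncated geometric law (mean
#' about 3 litters per pair, maximum 12), so parity runs over its full
#' 1..12 range as in a multi-year breeding program; litters are
#' assigned uniformly to the 48 batches; each litter receives a latent
#' log rate `eta + eps` with `eps ~ N(0, sigma2)` and a weaned size
#' drawn from the zero-truncated Poisson at that rate.
#'
#' @param truth a [default_truth()]-style `"sim_truth"`.
#' @param seed integer RNG seed.
#' @return A litter-record data frame in the canonical schema
#'   (`dam_strain`, `sire_strain`, `dam_id`, `sire_id`, `batch`,
#'   `parity`, `litter_size`), which passes [validate_records()] with no
#'   drops.
#' @export
simulate_litters <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(as.integer(seed))
  strains <- truth$strains
  des <- truth$design
  rows <- lapply(seq_len(nrow(des)), function(i) {
    nl <- des$n_litters[i]
    # litters per mating pair: geometric (success 1/3) truncated to 1..12
    sizes <- integer(0)
    while (sum(sizes) < nl)
      sizes <- c(sizes, pmin(stats::rgeom(nl, 1 / 3) + 1L, 12L))
    sizes <- sizes[cumsum(sizes) - sizes < nl]
    pair_of <- rep(seq_along(sizes), sizes)[seq_len(nl)]
    parity <- stats::ave(pair_of, pair_of, FUN = seq_along)
    tag <- sprintf("%s.%s.p%03d", des$dam[i], des$sire[i], pair_of)
    data.frame(dam_strain = des$dam[i], sire_strain = des$sire[i],
               dam_id = paste0(tag, ".f"), sire_id = paste0(tag, ".m"),
               batch = sample.int(48L, nl, replace = TRUE),
               parity = as.integer(pmin(parity, 12L)),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  j <- strain_index(rec$dam_strain, strains)
  k <- strain_index(rec$sire_strain, strains)
  eta <- state_eta(truth$state, j, k, rec$parity, rec$batch, strains)
  lat <- eta + stats::rnorm(nrow(rec), 0, sqrt(truth$state$sigma2))
  rec$litter_size <- rztp(nrow(rec), exp(lat))
  rownames(rec) <- NULL
  rec
}

#' Add sex counts to simulated litters
#'
#' Draws male counts per litter from the binomial sex-ratio model: the
#' latent logit male proportion follows the truth's sex-ratio effect
#' state plus litter-level noise, and `n_male ~ Binom(litter_size,
#' expit(latent))`; `n_female` is the remainder.
#'
#' @param records simulated litter records (with `litter_size`).
#' @param truth a `"sim_truth"` whose `sexratio` state to use.
#' @param seed integer RNG seed.
#' @return `records` with `n_male` and `n_female` columns added.
#' @export
simulate_sex <- function(records, truth, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(as.integer(seed))
  strains <- truth$strains
  j <- strain_index(records$dam_strain, strains)
  k <- strain_index(records$sire_strain, strains)
  eta <- state_eta(truth$sexratio, j, k, records$parity, records$batch,
                   strains)
  lat <- eta + stats::rnorm(nrow(records), 0, sqrt(truth$sexratio$sigma2))
  records$n_male <- stats::rbinom(nrow(records), records$litter_size,
                                  stats::plogis(lat))
  records$n_female <- records$litter_size - records$n_male
  records
}
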