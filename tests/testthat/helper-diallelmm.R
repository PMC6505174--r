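# Shared fixtures, built in code.

# scratch space shared across acceptance blocks (avoids refitting)
.acceptance_cache <- new.env(parent = emptyenv())

# a small record table over a few crosses
toy_records <- function(n_per = 3, crosses = list(c("AJ", "B6"),
                                                  c("B6", "AJ"),
                                                  c("B6", "B6"))) {
  rows <- lapply(seq_along(crosses), function(i) {
    data.frame(dam_strain = crosses[[i]][1], sire_strain = crosses[[i]][2],
               dam_id = paste0("d", i), sire_id = paste0("s", i),
               batch = ((i - 1) %% 48) + 1, parity = ((i - 1) %% 12) + 1,
               litter_size = 5 + (seq_len(n_per) %% 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

quick_config <- function(seed, n_iter = 600, n_burn = 200, thin = 2,
                         n_chains = 1, ...) {
  fit_config(seed = seed, n_iter = n_iter, n_burn = n_burn, thin = thin,
             n_chains = n_chains, ...)
}

# a random effect state satisfying all sum-to-zero constraints
random_state <- function(scale = 1) {
  ctr <- function(x) x - mean(x)
  list(mu = rnorm(1), alpha = rnorm(1, sd = 0.02),
       beta_inbred = rnorm(1, sd = scale),
       a = ctr(rnorm(8, sd = scale)), m = ctr(rnorm(8, sd = scale)),
       b = ctr(rnorm(8, sd = scale)),
       v = ctr(rnorm(28, sd = scale)), w = ctr(rnorm(28, sd = scale)),
       order = rnorm(12, sd = 0.05), batch = rnorm(48, sd = 0.1),
       sigma2 = runif(1, 0.05, 0.5))
}

# population variance (division by n, the measure used over diallel cells)
pvar <- function(x) mean((x - mean(x))^2)

# Brute-force variance-projection oracle: enumerate all 64 cells directly
# from the effect vectors, never through the package's cell machinery.
brute_varp_classvars <- function(state) {
  add <- psx <- inbo <- inbs <- epv <- epw <- matrix(0, 8, 8)
  pair_of <- function(j, k) {
    lo <- min(j, k); hi <- max(j, k)
    cnt <- 0L
    for (jj in 1:7) for (kk in (jj + 1):8) {
      cnt <- cnt + 1L
      if (jj == lo && kk == hi) return(cnt)
    }
    stop("unreachable")
  }
  for (j in 1:8) for (k in 1:8) {
    add[j, k] <- state$a[j] + state$a[k]
    if (j == k) {
      inbo[j, k] <- state$beta_inbred
      inbs[j, k] <- state$b[j]
    } else {
      psx[j, k] <- state$m[j] - state$m[k]
      p <- pair_of(j, k)
      epv[j, k] <- state$v[p]
      epw[j, k] <- (if (j < k) 0.5 else -0.5) * state$w[p]
    }
  }
  c(additive = pvar(add), parental_sex = pvar(psx),
    inbred_overall = pvar(inbo), inbred_strain = pvar(inbs),
    epistatic_symmetric = pvar(epv), epistatic_asymmetric = pvar(epw))
}

# wrap a parameter vector list into a minimal diallel_fit whose draw matrix
# repeats the state (handy for summarization tests without MCMC)
fake_fit <- function(states, model = "ztp",
                     strains = diallel_strains()) {
  pl <- strain_pairs(strains)$label
  nm <- c("mu", "alpha", "beta_inbred",
          paste0("a.", strains), paste0("m.", strains), paste0("b.", strains),
          paste0("v.", pl), paste0("w.", pl),
          paste0("order.", 1:12), paste0("batch.", 1:48),
          "sigma2", paste0("tau2.", c("a", "m", "b", "v", "w", "batch",
                                      "order")))
  rows <- t(vapply(states, function(s) {
    c(s$mu, s$alpha, s$beta_inbred, s$a, s$m, s$b, s$v, s$w,
      s$order, s$batch, s$sigma2, rep(0.1, 7))
  }, numeric(length(nm))))
  colnames(rows) <- nm
  structure(list(draws = rows, chain = rep(1L, nrow(rows)), model = model,
                 config = fit_config(seed = 1, n_iter = 2, n_burn = 0,
                                     thin = 1, n_chains = 1),
                 strains = strains, n_obs = 0L),
            class = "diallel_fit")
}
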