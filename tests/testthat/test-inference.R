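test_that("fit_config enforces its contract", {
  expect_error(fit_config(), "seed")
  expect_error(fit_config(seed = 1, n_iter = 100, n_burn = 200), "n_iter")
  expect_error(fit_config(seed = 1, classes = "q"), "unknown class")
})

test_that("sum-to-zero draws live on the hyperplane with projected variance", {
  set.seed(5)
  # K = 2: the constrained draw is (x, -x)
  d2 <- draw_sum_to_zero(c(1, 2), c(1, 1))
  expect_equal(d2[1], -d2[2])
  expect_error(draw_sum_to_zero(1, 1), "at least 2")
  # prior-only draws at tau2 = 1, K = 8: per-coordinate variance (K-1)/K
  tau2 <- 1; K <- 8
  draws <- t(replicate(20000, draw_sum_to_zero(numeric(K), rep(1 / tau2, K))))
  expect_true(all(abs(rowSums(draws)) < 1e-12))
  expect_equal(mean(apply(draws, 2, var)), tau2 * (K - 1) / K,
               tolerance = 0.03)
  # dense-precision path agrees with the diagonal path in distribution
  P <- diag(4) * 2
  dd <- t(replicate(5000, draw_sum_to_zero(numeric(4), P)))
  expect_true(all(abs(rowSums(dd)) < 1e-12))
  expect_equal(mean(apply(dd, 2, var)), 0.5 * 3 / 4, tolerance = 0.06)
})

test_that("fits are bit-identical under a fixed seed and config", {
  rec <- simulate_litters(default_truth(1), 2)[1:300, ]
  cfg <- quick_config(seed = 9)
  f1 <- fit_ztp_diallel(rec, config = cfg)
  f2 <- fit_ztp_diallel(rec, config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ztp_diallel(rec, config = quick_config(seed = 10))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every retained draw satisfies the sum-to-zero constraints", {
  tr <- default_truth(2)
  rec <- simulate_sex(simulate_litters(tr, 3)[1:400, ], tr, 4)
  for (fit in list(
    fit_ztp_diallel(rec, config = quick_config(seed = 1)),
    fit_gaussian_diallel(rec, config = quick_config(seed = 2)),
    fit_binomial_diallel(rec, config = quick_config(seed = 3)))) {
    d <- fit$draws
    for (cls in c("a", "m", "b", "v", "w")) {
      sums <- rowSums(d[, grep(paste0("^", cls, "\\."), colnames(d)),
                        drop = FALSE])
      expect_lt(max(abs(sums)), 1e-10)
    }
    expect_true(all(d[, "sigma2"] > 0))
    expect_true(all(d[, grep("^tau2\\.", colnames(d))] > 0))
  }
})

test_that("input validation rejects impossible outcomes", {
  rec <- toy_records()
  rec$litter_size[1] <- 0
  expect_error(fit_ztp_diallel(rec, config = quick_config(seed = 1)),
               "positive integers")
  rec <- toy_records()
  rec$n_male <- rec$litter_size + 1
  expect_error(fit_binomial_diallel(rec, config = quick_config(seed = 1)),
               "n_male <= litter_size")
})

test_that("gaussian fitter matches the conjugate posterior on an intercept-only toy", {
  # y ~ N(mu, sigma2), mu ~ N(0, 1000): given sigma2 the posterior mean of mu
  # is (n ybar / sigma2) / (n / sigma2 + 1/1000). With every effect class
  # disabled the sampler reduces to exactly this model.
  set.seed(81)
  y <- rnorm(50, mean = 3, sd = 1)
  rec <- data.frame(dam_strain = "AJ", sire_strain = "B6",
                    batch = 1, parity = 1, litter_size = 1)
  rec <- rec[rep(1, 50), ]
  rec$litter_size <- y   # identity transform fits the raw response
  fit <- fit_gaussian_diallel(rec, transform = "identity",
                              config = fit_config(seed = 4, n_iter = 6000,
                                                  n_burn = 1000, thin = 1,
                                                  n_chains = 1,
                                                  classes = character(0)))
  mu_draws <- fit$draws[, "mu"]
  s2_hat <- mean(fit$draws[, "sigma2"])
  n <- length(y)
  conj_mean <- (n * mean(y) / s2_hat) / (n / s2_hat + 1 / 1000)
  mcse <- sd(mu_draws) / sqrt(length(mu_draws) / 10)  # conservative ESS
  expect_lt(abs(mean(mu_draws) - conj_mean), 3 * mcse + 1e-3)
  # posterior sd close to the conjugate value at the posterior-mean sigma2
  conj_sd <- sqrt(1 / (n / s2_hat + 1 / 1000))
  expect_equal(sd(mu_draws), conj_sd, tolerance = 0.15)
})

test_that("identity transform on sqrt data equals sqrt transform on raw data", {
  rec <- simulate_litters(default_truth(3), 5)[1:200, ]
  rec_pre <- rec
  rec_pre$litter_size <- sqrt(rec$litter_size)
  f1 <- fit_gaussian_diallel(rec, transform = "sqrt",
                             config = quick_config(seed = 11))
  f2 <- fit_gaussian_diallel(rec_pre, transform = "identity",
                             config = quick_config(seed = 11))
  expect_identical(f1$draws, f2$draws)
})

test_that("prior-only run reproduces the fixed-effect prior scale", {
  rec <- toy_records()[0, ]
  fit <- fit_gaussian_diallel(rec,
                              config = fit_config(seed = 12, n_iter = 4000,
                                                  n_burn = 500, thin = 1,
                                                  n_chains = 1,
                                                  classes = character(0)))
  # mu and beta_inbred are independent N(0, 1000) draws with no data
  expect_equal(sd(fit$draws[, "mu"]), sqrt(1000), tolerance = 0.1)
  expect_equal(sd(fit$draws[, "beta_inbred"]), sqrt(1000), tolerance = 0.1)
  expect_lt(abs(mean(fit$draws[, "mu"])), 3 * sqrt(1000 / 3500) * 2)
})

test_that("ztp and gaussian fitters agree on strain-effect ranking", {
  tr <- default_truth(4)
  rec <- simulate_litters(tr, 6)
  cfg <- fit_config(seed = 13, n_iter = 2500, n_burn = 500, thin = 2,
                    n_chains = 1)
  fz <- fit_ztp_diallel(rec, config = cfg)
  fg <- fit_gaussian_diallel(rec, config = cfg)
  az <- colMeans(fz$draws[, grep("^a\\.", colnames(fz$draws))])
  ag <- colMeans(fg$draws[, grep("^a\\.", colnames(fg$draws))])
  expect_gt(cor(az, ag, method = "spearman"), 0.8)
  expect_true(all(sign(az[abs(az) > 0.05]) ==
                    sign(ag[names(az)[abs(az) > 0.05]])))
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  set.seed(21)
  good <- cbind(x = rnorm(4000))
  cd <- convergence_diagnostics(good, chain = rep(1:2, each = 2000))
  expect_lt(abs(cd$psrf - 1), 0.02)
  expect_false(cd$flagged)
  bad <- cbind(x = c(rnorm(2000), rnorm(2000, mean = 10)))
  cd2 <- convergence_diagnostics(bad, chain = rep(1:2, each = 2000))
  expect_gt(cd2$psrf, 2)
  expect_true(cd2$flagged)
  expect_warning(convergence_diagnostics(good, chain = rep(1, 4000)),
                 "one chain")
})

test_that("effective sample size is right for an AR(1) chain", {
  set.seed(22)
  n <- 50000; rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), n))
  cd <- suppressWarnings(
    convergence_diagnostics(cbind(x = x), chain = rep(1, n)))
  expect_equal(cd$ess, n * (1 - rho) / (1 + rho), tolerance = 0.2)
})
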