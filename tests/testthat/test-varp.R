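test_that("class contribution matrices have the declared structure", {
  zero <- random_state(0)
  zero$beta_inbred <- 0
  cc0 <- class_contributions(zero)
  for (mat in cc0) expect_equal(unname(mat), matrix(0, 8, 8))

  # additive cancellation: a1 = c, a2 = -c makes cell (1,2) zero
  st <- random_state(0)
  st$a <- c(0.7, -0.7, rep(0, 6))
  cc <- class_contributions(st)
  expect_equal(cc$additive[1, 2], 0)
  expect_equal(cc$additive[1, 1], 1.4)

  set.seed(51)
  st <- random_state()
  cc <- class_contributions(st)
  expect_equal(unname(cc$parental_sex), -t(unname(cc$parental_sex)))
  expect_equal(unname(cc$epistatic_symmetric),
               t(unname(cc$epistatic_symmetric)))
  expect_equal(diag(cc$epistatic_symmetric), rep(0, 8),
               ignore_attr = TRUE)
  expect_equal(unname(cc$epistatic_asymmetric),
               -t(unname(cc$epistatic_asymmetric)))
  off <- upper.tri(cc$inbred_overall) | lower.tri(cc$inbred_overall)
  expect_true(all(cc$inbred_overall[off] == 0))
  expect_equal(diag(cc$inbred_overall), rep(st$beta_inbred, 8),
               ignore_attr = TRUE)
})

test_that("variance projections equal the brute-force 64-cell oracle", {
  set.seed(52)
  for (rep in 1:100) {
    st <- random_state(runif(1, 0.1, 2))
    fit <- fake_fit(list(st, st))
    vp <- compute_varp(fit)
    oracle <- brute_varp_classvars(st)
    denom <- sum(oracle) + pvar(st$batch) + pvar(st$order) + st$sigma2
    got <- vp$fractions[1, names(oracle)]
    expect_equal(unname(got), unname(oracle / denom), tolerance = 1e-12)
  }
})

test_that("fractions sum to one per draw and degenerate states behave", {
  set.seed(53)
  states <- replicate(40, random_state(), simplify = FALSE)
  vp <- compute_varp(fake_fit(states))
  tot <- rowSums(vp$fractions[, !colnames(vp$fractions) %in%
                                "total_explained", drop = FALSE])
  expect_lt(max(abs(tot - 1)), 1e-10)
  expect_true(all(vp$fractions >= 0 & vp$fractions <= 1 + 1e-12))

  # only noise: residual fraction 1
  noise <- random_state(0)
  noise$beta_inbred <- 0; noise$order <- numeric(12); noise$batch <- numeric(48)
  vpn <- compute_varp(fake_fit(list(noise, noise)))
  expect_equal(unname(vpn$fractions[1, "residual"]), 1, tolerance = 1e-12)
  expect_equal(unname(vpn$fractions[1, "total_explained"]), 0,
               tolerance = 1e-12)

  # only additive effects: additive fraction 1
  addo <- random_state(0)
  addo$beta_inbred <- 0; addo$order <- numeric(12); addo$batch <- numeric(48)
  addo$sigma2 <- 1e-300
  addo$a <- c(1, -1, rep(0, 6))
  vpa <- compute_varp(fake_fit(list(addo, addo)))
  expect_equal(unname(vpa$fractions[1, "additive"]), 1, tolerance = 1e-9)
})

test_that("dam/sire projection partitions exactly the additive + parental share", {
  set.seed(54)
  states <- replicate(30, random_state(), simplify = FALSE)
  fit <- fake_fit(states)
  vp <- compute_varp(fit)
  vds <- varp_dam_sire(fit)
  lhs <- vds$fractions[, "dam_strain"] + vds$fractions[, "sire_strain"]
  rhs <- vp$fractions[, "additive"] + vp$fractions[, "parental_sex"]
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  for (cls in c("inbred_overall", "inbred_strain", "epistatic_symmetric",
                "epistatic_asymmetric", "batch", "order", "residual")) {
    expect_equal(unname(vds$fractions[, cls]), unname(vp$fractions[, cls]),
                 tolerance = 1e-12)
  }
  # m = 0: dam and sire fractions coincide; a = 0 likewise
  st <- random_state(); st$m <- numeric(8)
  v1 <- varp_dam_sire(fake_fit(list(st, st)))
  expect_equal(unname(v1$fractions[1, "dam_strain"]),
               unname(v1$fractions[1, "sire_strain"]), tolerance = 1e-12)
  st2 <- random_state(); st2$a <- numeric(8)
  v2 <- varp_dam_sire(fake_fit(list(st2, st2)))
  expect_equal(unname(v2$fractions[1, "dam_strain"]),
               unname(v2$fractions[1, "sire_strain"]), tolerance = 1e-12)
})

test_that("fractions are invariant to a common scale on effects and noise", {
  set.seed(55)
  st <- random_state()
  st2 <- st
  cfac <- 3.7
  for (f in c("beta_inbred", "a", "m", "b", "v", "w", "order", "batch"))
    st2[[f]] <- st[[f]] * cfac
  st2$sigma2 <- st$sigma2 * cfac^2
  f1 <- compute_varp(fake_fit(list(st, st)))$fractions[1, ]
  f2 <- compute_varp(fake_fit(list(st2, st2)))$fractions[1, ]
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)
})

test_that("the denominator classes are switchable", {
  set.seed(56)
  st <- random_state()
  fit <- fake_fit(list(st, st))
  full <- compute_varp(fit, include = c("batch", "order"))
  bare <- compute_varp(fit, include = character(0))
  expect_false("batch" %in% colnames(bare$fractions))
  expect_gt(unname(bare$fractions[1, "total_explained"]),
            unname(full$fractions[1, "total_explained"]))
})
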