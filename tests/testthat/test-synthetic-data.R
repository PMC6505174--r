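test_that("default truth encodes the reference breeding design", {
  tr <- default_truth(1)
  des <- tr$design
  expect_equal(nrow(des), 62)                    # 62 viable crosses
  expect_false(any(des$dam == "NZO" & des$sire %in% c("CAST", "PWK")))
  expect_true(any(des$dam == "CAST" & des$sire == "NZO"))  # reciprocals exist
  expect_equal(sum(des$n_litters), 4448)
  diag_n <- des$n_litters[des$dam == des$sire]
  off_n <- des$n_litters[des$dam != des$sire]
  expect_gt(min(diag_n) / max(off_n), 4)         # diagonal-heavy
})

test_that("default truth satisfies all effect-state constraints", {
  tr <- default_truth(3)
  st <- tr$state
  for (f in c("a", "m", "b", "v", "w"))
    expect_lt(abs(sum(st[[f]])), 1e-10)
  expect_gt(st$sigma2, 0)
  expect_lt(st$beta_inbred, 0)                   # inbreeding penalty
  expect_equal(st$mu, log(5.46))
  # B6 and NOD maternal lines raise litter size; wild-derived dams lower it
  dam <- st$a + st$m
  expect_true(all(dam[c("B6", "NOD")] > 0.2))
  expect_true(all(dam[c("CAST", "PWK", "WSB")] < -0.1))
})

test_that("truth calibration hits the declared variance fractions", {
  tr <- default_truth(7)
  st <- tr$state
  cls <- brute_varp_classvars(st)
  denom <- sum(cls) + pvar(st$batch) + pvar(st$order) + st$sigma2
  fr <- tr$target_fracs
  expect_equal(unname(cls["additive"] / denom), unname(fr[["additive"]]),
               tolerance = 1e-9)
  expect_equal(unname(cls["parental_sex"] / denom),
               unname(fr[["parental_sex"]]), tolerance = 1e-9)
  expect_equal(unname(cls["inbred_overall"] / denom),
               unname(fr[["inbred_overall"]]), tolerance = 1e-9)
  expect_equal(unname(sum(cls[c("epistatic_symmetric",
                                "epistatic_asymmetric")]) / denom),
               unname(fr[["epistatic_symmetric"]] +
                        fr[["epistatic_asymmetric"]]), tolerance = 1e-9)
  dam <- st$a + st$m; sire <- st$a - st$m
  expect_equal(pvar(dam) / denom, 0.1315, tolerance = 1e-6)
  expect_equal(pvar(sire) / denom, 0.0180, tolerance = 1e-6)
  # identical calibration whatever the seed of the haphazard parts
  tr2 <- default_truth(8)
  cls2 <- brute_varp_classvars(tr2$state)
  denom2 <- sum(cls2) + pvar(tr2$state$batch) + pvar(tr2$state$order) +
    tr2$state$sigma2
  expect_equal(cls2["additive"] / denom2, cls["additive"] / denom,
               tolerance = 1e-9)
})

test_that("simulated litters honor the generative law", {
  tr <- default_truth(1)
  rec <- simulate_litters(tr, 5)
  expect_equal(nrow(rec), 4448)
  expect_true(all(rec$litter_size >= 1))
  expect_true(all(rec$parity >= 1 & rec$parity <= 12))
  expect_true(all(rec$batch >= 1 & rec$batch <= 48))
  v <- validate_records(rec)
  expect_equal(sum(v$report$n_dropped), 0)        # generator output is clean
  # deterministic under the seed
  expect_identical(rec, simulate_litters(tr, 5))
  expect_false(identical(rec$litter_size,
                         simulate_litters(tr, 6)$litter_size))
})

test_that("a null truth reproduces the ztp mean; dam effects act monotonically", {
  tr <- default_truth(1)
  null <- tr
  null$state <- random_state(0)
  null$state$mu <- log(5); null$state$beta_inbred <- 0
  null$state$order <- numeric(12); null$state$batch <- numeric(48)
  null$state$sigma2 <- 1e-12
  null$design$n_litters <- rep(200L, nrow(null$design))
  rec <- simulate_litters(null, 8)
  mu <- ztp_mean(5)
  ys <- 1:100
  vr <- sum(ys^2 * dztp(ys, 5)) - mu^2
  expect_lt(abs(mean(rec$litter_size) - mu), 3 * sqrt(vr / nrow(rec)))

  # doubling a dam effect raises that dam strain's mean litter size
  up <- null
  up$state$a <- c(0.25, rep(-0.25 / 7, 7))
  up$state$m <- c(0.25, rep(-0.25 / 7, 7))
  rec_up <- simulate_litters(up, 8)
  m_base <- mean(rec$litter_size[rec$dam_strain == "AJ"])
  m_up <- mean(rec_up$litter_size[rec_up$dam_strain == "AJ"])
  expect_gt(m_up, m_base)
})

test_that("sex simulation is binomial around the truth and internally consistent", {
  tr <- default_truth(1)
  rec <- simulate_sex(simulate_litters(tr, 9), tr, 10)
  expect_true(all(rec$n_male + rec$n_female == rec$litter_size))
  expect_true(all(rec$n_male >= 0))
  ptrue <- plogis(qlogis(0.4979))
  tot <- sum(rec$litter_size)
  expect_lt(abs(sum(rec$n_male) / tot - ptrue), 3 * sqrt(0.25 / tot) + 0.01)

  # a maternal-line logit shift biases that strain's litters male
  biased <- tr
  biased$sexratio$m <- c(0.3, rep(-0.3 / 7, 7))
  biased$sexratio$a <- numeric(8)
  rec_b <- simulate_sex(simulate_litters(tr, 9), biased, 10)
  aj <- rec_b$dam_strain == "AJ" & rec_b$sire_strain != "AJ"
  expect_gt(sum(rec_b$n_male[aj]) / sum(rec_b$litter_size[aj]), 0.5)
})
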