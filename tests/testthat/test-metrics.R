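test_that("deaths and allocation at a cut count the first n_cut patients", {
  s <- tiny_scenario()
  J <- s$n_blocks; K <- 2L; L <- 2L
  counts <- array(0L, c(J, K, L)); counts[, , 1] <- 5L; counts[, , 2] <- 5L
  deaths <- array(0L, c(J, K, L))
  h0 <- fake_history(s, counts, deaths)
  expect_equal(deaths_at(h0, 100), 0)

  deaths_all <- counts
  h1 <- fake_history(s, counts, deaths_all)
  expect_equal(deaths_at(h1, total_patients(s)), total_patients(s))
  # block-aligned cut: first 3 blocks of 20
  expect_equal(deaths_at(h1, 60), 60)
  # mid-block cut is pro rata
  expect_equal(deaths_at(h1, 70), 70)

  expect_equal(allocation_proportion(h0, 2, 100), 0.5)
  expect_equal(allocation_proportion(h0, "arm1", 60, scope = "a"), 0.5)
  props <- vapply(1:2, function(l) allocation_proportion(h0, l, 120), 0)
  expect_equal(sum(props), 1)
})

test_that("fixed-randomisation deaths match the mixture-expectation oracle", {
  s <- recovery_two_arm()
  p <- mixture_rates(s)
  b <- run_batch(s, rar_policy("FeR"), n_reps = 100, base_seed = 14)
  d <- vapply(b, deaths_at, 0, n_cut = 6400)
  oracle <- 6400 * mean(p)   # 1556.6
  expect_equal(oracle, 1556.6, tolerance = 1e-3)
  expect_lt(abs(mean(d) - oracle), 3 * stats::sd(d) / sqrt(length(d)))

  # FuR allocates 1/3 to dexamethasone
  bf <- run_batch(s, rar_policy("FuR"), n_reps = 60, base_seed = 15)
  ap <- vapply(bf, allocation_proportion, 0, arm = 2, n_cut = 6400)
  expect_lt(abs(mean(ap) - 1 / 3), 3 * stats::sd(ap) / sqrt(length(ap)))
})

test_that("the Wald test equals a logistic regression fit and handles separation", {
  s <- tiny_scenario()
  J <- s$n_blocks
  counts <- array(0L, c(J, 2, 2)); counts[, , ] <- 5L
  deaths <- array(0L, c(J, 2, 2))
  deaths[, , 1] <- 2L; deaths[, , 2] <- 1L
  h <- fake_history(s, counts, deaths)
  tt <- treatment_test(h, 120, 2)
  # oracle: glm on the aggregated 2x2 table
  n1 <- 60; d1 <- 12; n0 <- 60; d0 <- 24
  fit <- stats::glm(cbind(c(d1, d0), c(n1 - d1, n0 - d0)) ~ c(1, 0),
                    family = stats::binomial())
  z <- summary(fit)$coefficients[2, 3]
  expect_equal(tt$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-6)
  expect_equal(tt$estimate, d0 / n0 - d1 / n1)
  expect_identical(tt$method, "wald")

  # identical empirical rates: no rejection, zero effect
  deaths[, , 2] <- 2L
  h_eq <- fake_history(s, counts, deaths)
  tt_eq <- treatment_test(h_eq, 120, 2)
  expect_false(tt_eq$reject)
  expect_equal(tt_eq$estimate, 0)

  # zero cell triggers the score fallback
  deaths[, , 2] <- 0L
  h_sep <- fake_history(s, counts, deaths)
  tt_sep <- treatment_test(h_sep, 120, 2)
  expect_identical(tt_sep$method, "score")
  expect_true(is.finite(tt_sep$p_value))

  # no deaths anywhere: no information, never rejects
  deaths[, , ] <- 0L
  tt_none <- treatment_test(fake_history(s, counts, deaths), 120, 2)
  expect_false(tt_none$reject)
})

test_that("simulated power tracks the asymptotic two-proportion oracle", {
  # one-stratum trial, 500 per arm at the cut, ventilated-subgroup rates
  s <- scenario(c("ctrl", "trt"), "all", matrix(c(0.414, 0.293), 1), 1,
                block_size = 100, n_blocks = 12, metric_cut_fraction = 1,
                schedule = adaptation_schedule(2, 2, 1))
  b <- run_batch(s, rar_policy("FeR"), n_reps = 300, base_seed = 16)
  rej <- vapply(b, function(h) treatment_test(h, 1000, 2)$reject, TRUE)
  p0 <- 0.414; p1 <- 0.293; n <- 500
  lor <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  se <- sqrt(1 / (n * p0 * (1 - p0)) + 1 / (n * p1 * (1 - p1)))
  oracle <- stats::pnorm(abs(lor) / se - stats::qnorm(0.975))
  expect_lt(abs(mean(rej) - oracle), 0.05)
})

test_that("bias and MSE follow their defining formulas", {
  expect_equal(relative_bias(rep(0.03, 5), 0.25, 0.22), 0)
  expect_equal(relative_bias(0.022, 0.27, 0.25), 0.1)
  expect_error(relative_bias(0.01, 0.3, 0.3), "undefined")

  expect_equal(mse(0.05, 0.05), 0)
  expect_equal(mse(c(0.05 + 1e-3, 0.05 - 1e-3), 0.05), 1e-6)
  expect_error(mse(numeric(0), 0.1), "at least one")
})

test_that("Neyman allocation favours the noisier arm and gives the 51/49 split", {
  expect_equal(neyman_allocation(0.3, 0.3), 0.5)
  expect_equal(neyman_allocation(0.5, 0.1), 0.625)
  s <- recovery_two_arm()
  p <- mixture_rates(s)
  expect_equal(round(neyman_allocation(p[1], p[2]), 2), 0.51)
  expect_error(neyman_allocation(0, 0.5), "inside")
})

test_that("aggregation summarises replicates with valid standard errors", {
  s <- tiny_scenario()
  b <- run_batch(s, rar_policy("T_f"), n_reps = 30, base_seed = 17)
  oc <- operating_characteristics(b)
  m <- oc$metrics
  expect_true(all(m$se >= 0))
  rej <- m$mean[m$metric == "reject"]
  expect_true(all(rej >= 0 & rej <= 1))
  expect_equal(oc$n_reps, 30)
  expect_equal(oc$n_cut, metric_cut(s))
  expect_false(is.na(oc_value(oc, "deaths")))

  # identical histories: zero SEs
  b2 <- structure(list(b[[1]], b[[1]]), class = "rar_batch",
                  policy = "T_f", base_seed = 0)
  oc2 <- operating_characteristics(b2)
  expect_true(all(oc2$metrics$se == 0))

  # cumulative deaths are monotone across block-end cuts
  h <- b[[5]]
  cuts <- seq_len(s$n_blocks) * s$block_size
  traj <- vapply(cuts, function(ct) deaths_at(h, ct), 0)
  expect_true(all(diff(traj) >= 0))
})

test_that("four-arm aggregation applies the Bonferroni familywise test", {
  s4 <- tiny_scenario(4L)
  b4 <- run_batch(s4, rar_policy("FeR4"), n_reps = 20, base_seed = 18)
  oc4 <- operating_characteristics(b4)
  expect_false(is.na(oc_value(oc4, "fwer", "cohort", NA)))
  rej_dex <- oc_value(oc4, "reject", "cohort", "arm1")
  expect_true(rej_dex >= 0 && rej_dex <= 1)
  # FWER is at least each single-arm rejection rate
  for (a in paste0("arm", 1:3))
    expect_gte(oc_value(oc4, "fwer", "cohort", NA) + 1e-12,
               oc_value(oc4, "reject", "cohort", a))
})
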