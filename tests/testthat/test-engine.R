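test_that("adaptation blocks start after burn-in and repeat on the cadence", {
  sched <- adaptation_schedule(burn_in = 34, cadence = 7, lag = 28)
  expect_identical(adaptation_blocks(sched, 100),
                   as.integer(c(35, 42, 49, 56, 63, 70, 77, 84, 91, 98)))
  expect_identical(adaptation_blocks(sched, 36), 35L)
  expect_identical(adaptation_blocks(sched, 30), integer(0))
  # burn-in covers 34 blocks x 80 patients = 2720 patients (42.5% of 6400)
  s <- recovery_two_arm()
  expect_equal(s$schedule$burn_in * s$block_size, 2720)
  expect_equal(2720 / total_patients(s), 0.34)
})

test_that("the observed window lags the endpoint and excludes the current block", {
  expect_identical(observed_window(35, 28), 1:7)
  expect_identical(observed_window(28, 28), integer(0))
  expect_identical(observed_window(98, 28), 1:70)
  expect_identical(observed_window(1, 0), integer(0))   # nothing allocated yet
  expect_identical(observed_window(5, 0), 1:4)
})

test_that("fixed policies never deviate and adaptive policies hold 1:1 through burn-in", {
  s <- tiny_scenario()
  h_fix <- run_replicate(s, rar_policy("FeR"), seed = 2)
  expect_true(all(h_fix$alloc == 0.5))
  expect_equal(nrow(h_fix$adaptations), 0L)

  h_tf <- run_replicate(s, rar_policy("T_f"), seed = 2)
  burn <- s$schedule$burn_in
  expect_true(all(h_tf$alloc[seq_len(burn), , ] == 0.5))
  expect_true(all(h_tf$adaptations$block > burn))
  expect_setequal(unique(h_tf$adaptations$block),
                  adaptation_blocks(s$schedule, s$n_blocks))

  # four-arm adaptive burn-in: 0.4 control, 0.2 per experimental arm
  s4 <- tiny_scenario(4L)
  h4 <- run_replicate(s4, rar_policy("T_f4"), seed = 3)
  expect_true(all(h4$alloc[seq_len(burn), , 1] == 0.4))
  expect_true(all(abs(h4$alloc[seq_len(burn), , -1] - 0.2) < 1e-12))
  expect_true(all(h4$alloc[, , 1] == 0.4))  # control protected throughout
})

test_that("replicates are bit-reproducible and replicate seeds are order-independent", {
  s <- tiny_scenario()
  pol <- rar_policy("RMC_s")
  expect_identical(run_replicate(s, pol, seed = 77),
                   run_replicate(s, pol, seed = 77))

  b2 <- run_batch(s, pol, n_reps = 2, base_seed = 5)
  b2b <- run_batch(s, pol, n_reps = 2, base_seed = 5)
  expect_identical(b2[[1]], b2b[[1]])
  expect_identical(b2[[2]], b2b[[2]])
  b4 <- run_batch(s, pol, n_reps = 4, base_seed = 5)
  expect_identical(b2[[1]], b4[[1]])  # growing the batch changes nothing
  expect_equal(length(run_batch(s, pol, n_reps = 6, base_seed = 1)), 6)
})

test_that("patients are conserved within every block", {
  s <- tiny_scenario()
  for (nm in c("FuR", "T_s")) {
    h <- run_replicate(s, rar_policy(nm), seed = 10)
    per_block <- rowSums(h$counts, dims = 1)  # summed over subgroup and arm
    expect_true(all(per_block == s$block_size))
    expect_true(all(h$deaths <= h$counts))
  }
})

test_that("adaptations use only outcome-matured data (lag honesty)", {
  s <- tiny_scenario()
  h <- run_replicate(s, rar_policy("T_f"), seed = 21)
  lag <- s$schedule$lag
  for (j in unique(h$adaptations$block)) {
    w <- observed_window(j, lag)
    obs_c <- colSums(colSums(h$counts[w, , , drop = FALSE]))
    obs_d <- colSums(colSums(h$deaths[w, , , drop = FALSE]))
    th1 <- prob_best_two(arm_posterior(obs_d[2], obs_c[2] - obs_d[2]),
                         arm_posterior(obs_d[1], obs_c[1] - obs_d[1]))
    snap <- h$adaptations[h$adaptations$block == j, ]
    expect_equal(snap$theta[snap$arm == s$arm_names[2]], th1)
    a <- clip_two(tuning_prob_two(th1, j / s$n_blocks))
    expect_equal(snap$alloc_prob[snap$arm == s$arm_names[2]], a)
  }

  # subgroup scope adapts each stratum on its own window
  hs <- run_replicate(s, rar_policy("T_s"), seed = 22)
  j <- max(hs$adaptations$block)
  w <- observed_window(j, lag)
  for (k in 1:2) {
    obs_c <- colSums(matrix(hs$counts[w, k, ], ncol = 2))
    obs_d <- colSums(matrix(hs$deaths[w, k, ], ncol = 2))
    th1 <- prob_best_two(arm_posterior(obs_d[2], obs_c[2] - obs_d[2]),
                         arm_posterior(obs_d[1], obs_c[1] - obs_d[1]))
    snap <- hs$adaptations[hs$adaptations$block == j &
                           hs$adaptations$scope == s$subgroup_names[k], ]
    expect_equal(snap$theta[snap$arm == s$arm_names[2]], th1)
  }
})

test_that("posterior Monte-Carlo draws do not perturb patient-level streams", {
  s4 <- tiny_scenario(4L)
  h_a <- run_replicate(s4, rar_policy("T_f4", n_draws = 500), seed = 31)
  h_b <- run_replicate(s4, rar_policy("T_f4", n_draws = 5000), seed = 31)
  burn <- s4$schedule$burn_in
  # identical up to the first adaptation by stream isolation
  expect_identical(h_a$counts[seq_len(burn), , ], h_b$counts[seq_len(burn), , ])
  expect_identical(h_a$deaths[seq_len(burn), , ], h_b$deaths[seq_len(burn), , ])
})

test_that("with no lag, unit cadence and a theta stub the engine is a bandit loop", {
  s <- tiny_scenario()
  s$schedule <- adaptation_schedule(burn_in = 1, cadence = 1, lag = 0)
  pol <- rar_policy("T_f")
  pol$theta_fn <- function(deaths, counts) c(0, 1)  # arm 1 always "best"
  h <- run_replicate(s, pol, s$schedule, seed = 40)
  # from block 2 onward allocation sits at the 0.9 cap for the favoured arm
  expect_true(all(h$alloc[2:s$n_blocks, , 2] == 0.9))
  expect_true(all(h$alloc[1, , ] == 0.5))
})
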