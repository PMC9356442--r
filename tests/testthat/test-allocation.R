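test_that("fixed two-arm policies give the stated dexamethasone probabilities", {
  expect_equal(fixed_prob_two(rar_policy("FeR")), 1 / 2)
  expect_equal(fixed_prob_two(rar_policy("FuR")), 1 / 3)
  expect_equal(1 - fixed_prob_two(rar_policy("FuR")), 2 / 3)
  expect_error(fixed_prob_two(rar_policy("T_f")), "fixed two-arm")
})

test_that("the tuning rule interpolates between 1:1 and full exploitation", {
  for (s in c(0, 0.3, 1)) expect_equal(tuning_prob_two(0.5, s), 0.5)
  for (th in c(0.1, 0.6, 0.95)) expect_equal(tuning_prob_two(th, 1), th)
  expect_equal(tuning_prob_two(0.8, 0.5),
               sqrt(0.8) / (sqrt(0.8) + sqrt(0.2)))
  expect_equal(tuning_prob_two(0.8, 0.5), 2 / 3, tolerance = 1e-3)
  expect_equal(tuning_prob_two(0.9, 0), 0.5)  # trial start: no exploitation
})

test_that("the REMAP-CAP rule discounts arms with larger accrued samples", {
  expect_equal(remapcap_prob_two(0.5, 0.5, 120, 120), 0.5)
  expect_equal(remapcap_prob_two(1, 0, 10, 10), 1)
  expect_equal(remapcap_prob_two(0.8, 0.2, 99, 99),
               sqrt(0.008) / (sqrt(0.008) + sqrt(0.002)))
  expect_equal(remapcap_prob_two(0.8, 0.2, 99, 99), 2 / 3, tolerance = 1e-9)
  # same evidence, more patients on arm 1: allocation to arm 1 drops
  expect_lt(remapcap_prob_two(0.6, 0.4, 500, 100),
            remapcap_prob_two(0.6, 0.4, 100, 100))
  expect_error(remapcap_prob_two(0, 0, 5, 5), "undefined")
})

test_that("two-arm clipping bounds allocation to [0.1, 0.9]", {
  expect_equal(clip_two(0.95), 0.9)
  expect_equal(clip_two(0.5), 0.5)
  expect_equal(clip_two(0.02), 0.1)
  expect_equal(clip_two(c(0, 0.5, 1)), c(0.1, 0.5, 0.9))
})

test_that("multi-arm tuning and REMAP-CAP rules split the 0.6 budget", {
  expect_equal(tuning_prob_multi(c(0.2, 0.2, 0.2), 0.5), rep(0.2, 3))
  expect_equal(tuning_prob_multi(c(0.7, 0.2, 0.05), 0), rep(0.2, 3))
  expect_equal(tuning_prob_multi(c(0.9, 0.05, 0.05), 1), c(0.54, 0.03, 0.03))
  expect_equal(sum(tuning_prob_multi(c(0.8, 0.15, 0.05), 0.37)), 0.6)

  expect_equal(remapcap_prob_multi(c(0.3, 0.3, 0.3), c(50, 50, 50)),
               rep(0.2, 3))
  w <- sqrt(c(0.8, 0.1, 0.1) / 100)
  expect_equal(remapcap_prob_multi(c(0.8, 0.1, 0.1), c(99, 99, 99)),
               0.6 * w / sum(w))
  expect_equal(remapcap_prob_multi(c(0.8, 0.1, 0.1), c(99, 99, 99)),
               c(0.351, 0.124, 0.124), tolerance = 5e-3)
  # doubling an arm's count strictly decreases its probability
  a <- remapcap_prob_multi(c(0.5, 0.3, 0.2), c(100, 100, 100))
  b <- remapcap_prob_multi(c(0.5, 0.3, 0.2), c(200, 100, 100))
  expect_lt(b[1], a[1])
})

test_that("the four-arm floor rule raises small arms at the maximum's expense", {
  expect_equal(clip_multi(c(0.50, 0.04, 0.06)), c(0.49, 0.05, 0.06))
  expect_equal(clip_multi(c(0.54, 0.03, 0.03)), c(0.50, 0.05, 0.05))
  expect_equal(clip_multi(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  # sum is preserved exactly
  x <- c(0.55, 0.04, 0.01)
  expect_equal(sum(clip_multi(x)), sum(x))
  expect_true(all(clip_multi(x) >= 0.05))
  # infeasible floor
  expect_error(clip_multi(c(0.05, 0.01, 0.01), floor = 0.3), "infeasible")
})

test_that("full allocation vectors are proper distributions with the stated shapes", {
  s2 <- recovery_two_arm(); s4 <- recovery_four_arm()
  expect_equal(full_allocation_vector(rar_policy("FuR4"), scen = s4),
               c(2 / 5, 1 / 5, 1 / 5, 1 / 5))
  expect_equal(full_allocation_vector(rar_policy("FeR4"), scen = s4),
               rep(1 / 4, 4))

  inputs2 <- list(theta = c(0.02, 0.98), arm_counts = c(300, 300), s = 0.9)
  v2 <- full_allocation_vector(rar_policy("T_f"), inputs2, s2)
  expect_equal(sum(v2), 1)
  expect_true(v2[2] <= 0.9 && v2[2] >= 0.1)  # clipped
  expect_equal(v2[2], 0.9)  # extreme evidence hits the cap

  inputs4 <- list(theta = c(0.01, 0.95, 0.02, 0.02),
                  arm_counts = c(500, 400, 300, 300), s = 0.9)
  for (nm in c("T_f4", "RMC_f4")) {
    v4 <- full_allocation_vector(rar_policy(nm), inputs4, s4)
    expect_equal(sum(v4), 1)
    expect_equal(v4[1], 0.4)            # control protected
    expect_true(all(v4[-1] >= 0.05))    # floor
  }
  expect_error(full_allocation_vector(rar_policy("T_f4"), inputs4, s2),
               "incompatible|expects 4 arms|4 arms")
})
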