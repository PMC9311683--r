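test_that("hit_probability handles degenerate spreads and windows", {
  w <- tolerance_window(990, 1100)
  p0 <- participant_params(1000, 100, lapse_rate = 0)
  expect_equal(hit_probability(p0, w),
               (pnorm(1) - pnorm(-0.1)) /
                 pnorm(0, 1000, 100, lower.tail = FALSE),
               tolerance = 1e-12)
  # point-mass responder inside / outside the window
  expect_equal(hit_probability(participant_params(1045, 0, lapse_rate = 0),
                               w), 1)
  expect_equal(hit_probability(participant_params(500, 0, lapse_rate = 0),
                               w), 0)
  # zero-width window with continuous spread carries no mass
  expect_equal(hit_probability(p0, tolerance_window(1045, 1045)), 0)
  # drift shifts the effective mean with the trial ordinal
  pd <- participant_params(1000, 100, lapse_rate = 0, drift_ms_per_trial = 1)
  expect_equal(hit_probability(pd, w, trial_number = 45),
               hit_probability(participant_params(1045, 100,
                                                  lapse_rate = 0), w))
})

test_that("equilibrium hit rate is widen / (widen + shrink)", {
  expect_equal(equilibrium_hit_rate(rule_hard()), 0.20)
  expect_equal(equilibrium_hit_rate(rule_easy()), 0.80)
  expect_equal(equilibrium_hit_rate(staircase_rule(5, 5)), 0.50)
})

test_that("the forward pass starts right, conserves mass and chains blocks", {
  p <- participant_params(1000, 100, lapse_rate = 0)
  w <- tolerance_window(990, 1100)
  one <- forward_accuracy_trajectory(p, rule_hard(), 1, start_window = w,
                                     score_policy = "all")
  expect_equal(one$trajectory, hit_probability(p, w))

  fwd <- forward_accuracy_trajectory(p, rule_hard(), 300, start_window = w)
  expect_equal(sum(fwd$final_distribution$mass) + fwd$pruned_loss, 1,
               tolerance = 1e-9)
  expect_lt(fwd$pruned_loss, 1e-8)
  expect_true(all(fwd$final_distribution$mass >= 0))
  expect_true(all(fwd$final_distribution$lower <=
                    fwd$final_distribution$upper))

  # chaining block 1 -> block 2 equals one uninterrupted pass under the
  # same rule
  b1 <- forward_accuracy_trajectory(p, rule_hard(), 40, start_window = w,
                                    score_policy = "all")
  b2 <- forward_accuracy_trajectory(p, rule_hard(), 40,
                                    start_distribution =
                                      b1$final_distribution,
                                    score_policy = "all")
  full <- forward_accuracy_trajectory(p, rule_hard(), 80, start_window = w,
                                      score_policy = "all")
  expect_equal(c(b1$trajectory, b2$trajectory), full$trajectory,
               tolerance = 1e-9)
})

test_that("trailing oracle accuracy converges to the rule equilibrium", {
  for (sd in c(50, 125, 200)) {
    p <- participant_params(1000, sd, lapse_rate = 0)
    fr <- forward_accuracy_trajectory(p, rule_hard(), 2000)
    expect_lt(abs(mean(tail(fr$trajectory, 500)) - 0.20), 0.02)
  }
  # and with a biased responder
  pb <- participant_params(900, 120, lapse_rate = 0)
  fr <- forward_accuracy_trajectory(pb, rule_hard(), 2000)
  expect_lt(abs(mean(tail(fr$trajectory, 500)) - 0.20), 0.02)
})

test_that("Monte-Carlo block accuracy agrees with the oracle expectation", {
  p <- participant_params(940, 110, lapse_rate = 0.02)
  oracle <- forward_accuracy_trajectory(p, rule_hard(), 80)
  n <- 3000
  set.seed(88)
  sim <- simulate_condition_accuracy(
    p, "confirmation", experiment_design(training_trials = 0), n, 1)
  # recompute the per-participant spread for a proper standard error
  resp <- matrix(sample_responses(p, rep(0L, 80 * 500)), nrow = 80)
  sw <- timestair:::.staircase_sweep(resp, 990, 1100, rule_hard())
  acc_i <- 100 * colMeans(sw$correct[-1, ])
  se <- sd(acc_i) / sqrt(n)
  expect_lt(abs(sim$mean_block1 - oracle$expected_accuracy), 3 * se)
})

test_that("calibration hits its target and reports unattainable ones", {
  cal <- calibrate_params(20, free = c("mean_ms", "sd_ms"))
  expect_lt(abs(attr(cal, "achieved_accuracy_pct") - 20), 0.5)
  # self-consistency with an independent forward pass
  refit <- forward_accuracy_trajectory(cal, rule_hard(), 80)
  expect_equal(refit$expected_accuracy, attr(cal, "achieved_accuracy_pct"),
               tolerance = 1e-9)

  cal_m <- calibrate_params(20, free = "mean_ms", sd_ms = 100)
  expect_equal(cal_m$sd_ms, 100)
  expect_lt(abs(attr(cal_m, "achieved_accuracy_pct") - 20), 0.5)

  cal_s <- calibrate_params(22, free = "sd_ms", mean_ms = 1000)
  expect_equal(cal_s$mean_ms, 1000)
  expect_lt(abs(attr(cal_s, "achieved_accuracy_pct") - 22), 0.5)

  # a 5% lapse floor caps attainable accuracy near 95%
  expect_error(calibrate_params(99.9, lapse_rate = 0.05),
               "unattainable")
  # the published block-1 band sits below the transient-plus-equilibrium
  # accuracy of an unbiased responder, so calibration must introduce bias
  cal16 <- calibrate_params(16.5)
  expect_gt(abs(cal16$mean_ms - 1045), 50)
})
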