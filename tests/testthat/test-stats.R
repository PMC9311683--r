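test_that("group summaries use sample SD and respect exclusions", {
  tab <- make_accuracy_table(rep("violation", 2), c(10, 30), c(50, 70))
  s <- summarize_cohort(tab)
  expect_equal(s$mean[s$block == "block1"], 20)
  expect_equal(s$sd[s$block == "block1"], sqrt(200), tolerance = 1e-9)
  expect_equal(round(s$sd[s$block == "block1"], 3), 14.142)

  same <- make_accuracy_table(rep("confirmation", 3), rep(12, 3), rep(15, 3))
  expect_equal(summarize_cohort(same)$sd, c(0, 0))

  tab$excluded <- c(FALSE, TRUE)
  s2 <- summarize_cohort(tab)
  expect_equal(s2$n, c(1, 1))
  expect_equal(s2$mean, c(10, 50))
  expect_error(summarize_cohort(tab[tab$excluded, ]), "no retained")
})

test_that("mean differences come straight from the summary cells", {
  s <- reference_accuracy_summary()
  expect_equal(posthoc_mean_difference(s, "confirmation", "violation")$m_diff,
               16.46 - 53.66)
  expect_equal(marginal_mean_difference(s, "violation", "violation")$m_diff,
               0)
  expect_error(posthoc_mean_difference(s, "confirmation", "nope"),
               "not found")
})

test_that("pooled-t post hoc machinery matches t.test in the 2-group case", {
  set.seed(9)
  tab <- make_accuracy_table(rep(c("confirmation", "violation"), each = 12),
                             rnorm(24, 16, 5), rnorm(24, c(16, 50), 8))
  s <- summarize_cohort(tab)
  res <- posthoc_mean_difference(s, "confirmation", "violation", "block2",
                                 data = tab, family = 1)
  tt <- t.test(accuracy_block2 ~ factor(condition, levels =
                                          c("confirmation", "violation")),
               data = tab, var.equal = TRUE)
  expect_equal(res$p_adjusted, tt$p.value, tolerance = 1e-12)
  expect_equal(res$ci_low, tt$conf.int[1], tolerance = 1e-9)
  expect_equal(res$ci_high, tt$conf.int[2], tolerance = 1e-9)
  # Bonferroni shrinks nothing for family 1, widens CI and p for family 6
  res6 <- posthoc_mean_difference(s, "confirmation", "violation", "block2",
                                  data = tab, family = 6)
  expect_gte(res6$p_adjusted, res$p_adjusted)
  expect_lt(res6$ci_low, res$ci_low)
  # CI always brackets the difference
  expect_lte(res6$ci_low, res6$m_diff)
  expect_gte(res6$ci_high, res6$m_diff)

  marg <- marginal_mean_difference(s, "confirmation", "violation",
                                   data = tab, family = 1)
  mt <- t.test((accuracy_block1 + accuracy_block2) / 2 ~
                 factor(condition, levels = c("confirmation", "violation")),
               data = tab, var.equal = TRUE)
  expect_equal(marg$p_adjusted, mt$p.value, tolerance = 1e-12)
})

test_that("mixed ANOVA reproduces the brute-force split-plot decomposition", {
  # 4-row fixture, sums of squares frozen from the hand decomposition:
  # group A subjects (1,2), (2,3); group B subjects (1,1), (2,2)
  tab <- make_accuracy_table(rep(c("A", "B"), each = 2),
                             c(1, 2, 1, 2), c(2, 3, 1, 2))
  fit <- mixed_anova(tab, contrasts = list())
  ss <- setNames(fit$anova$ss, fit$anova$effect)
  expect_equal(unname(ss["condition"]), 0.5)
  expect_equal(unname(ss["time"]), 0.5)
  expect_equal(unname(ss["time:condition"]), 0.5)
  expect_equal(fit$anova$ss_error, c(2, 0, 0))
  # the five SS components also tile the total sum of squares
  y <- c(tab$accuracy_block1, tab$accuracy_block2)
  expect_equal(sum(fit$anova$ss[1:3], fit$anova$ss_error[c(1, 2)]),
               sum((y - mean(y))^2))
  # independent brute-force oracle agrees
  oracle <- split_plot_ss(tab$condition, tab$accuracy_block1,
                          tab$accuracy_block2)
  expect_equal(unname(ss["condition"]), oracle$ss_condition)
  expect_equal(unname(ss["time"]), oracle$ss_time)
  expect_equal(unname(ss["time:condition"]), oracle$ss_interaction)
  expect_equal(fit$anova$ss_error[1], oracle$ss_subject_error)
  expect_equal(fit$anova$ss_error[2], oracle$ss_within_error)
  # degenerate limits: zero within error with effect present
  expect_equal(fit$anova$eta_sq_p[2], 1)
  expect_equal(fit$anova$F[2], Inf)
})

test_that("mixed ANOVA matches car's Type III repeated-measures tests", {
  skip_if_not_installed("car")
  set.seed(3)
  cond <- rep(c("confirmation", "violation", "violation_inhibiting",
                "violation_enhancing"), c(7, 9, 8, 10))
  tab <- make_accuracy_table(cond, rnorm(34, 16, 5),
                             rnorm(34, ifelse(cond == "confirmation",
                                              17, 50), 8))
  fit <- mixed_anova(tab)
  m <- lm(cbind(accuracy_block1, accuracy_block2) ~ condition, data = tab,
          contrasts = list(condition = "contr.sum"))
  aa <- car::Anova(m, idata = data.frame(time = factor(c("b1", "b2"))),
                   idesign = ~time, type = 3)
  uni <- summary(aa, multivariate = FALSE)$univariate.tests
  expect_equal(fit$anova$F[fit$anova$effect == "condition"],
               unname(uni["condition", "F value"]), tolerance = 1e-8)
  expect_equal(fit$anova$F[fit$anova$effect == "time"],
               unname(uni["time", "F value"]), tolerance = 1e-8)
  expect_equal(fit$anova$F[fit$anova$effect == "time:condition"],
               unname(uni["condition:time", "F value"]), tolerance = 1e-8)
  expect_equal(fit$anova$ss[fit$anova$effect == "time"],
               unname(uni["time", "Sum Sq"]), tolerance = 1e-8)
})

test_that("planned contrasts on difference scores behave like t tests", {
  set.seed(21)
  cond <- rep(c("confirmation", "violation"), each = 10)
  tab <- make_accuracy_table(cond, rnorm(20, 16, 4), rnorm(20, 30, 6))
  fit <- mixed_anova(tab, contrasts = list(cv = c(1, -1)))
  d <- tab$accuracy_block2 - tab$accuracy_block1
  tt <- t.test(d ~ cond, var.equal = TRUE)
  expect_equal(fit$contrasts$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$contrasts$p, tt$p.value, tolerance = 1e-10)

  # additive group shift with no time effect: condition clearly present,
  # time absent
  set.seed(5)
  shift <- rep(c(0, 25, 25, 25), each = 15)
  base <- rnorm(60, 16, 3)
  tab2 <- make_accuracy_table(
    rep(c("confirmation", "violation", "violation_inhibiting",
          "violation_enhancing"), each = 15),
    base + shift, base + shift + rnorm(60, 0, 3))
  fit2 <- mixed_anova(tab2)
  expect_lt(fit2$anova$eta_sq_p[fit2$anova$effect == "time"], 0.1)
  expect_lt(fit2$anova$p[fit2$anova$effect == "condition"], 1e-6)
  # partial eta squared identity for every effect
  expect_equal(fit2$anova$eta_sq_p,
               fit2$anova$ss / (fit2$anova$ss + fit2$anova$ss_error))
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.4, 5), 1)
  set.seed(1)
  p <- runif(50)
  adj <- bonferroni_adjust(p, 7)
  expect_true(all(adj >= p))
  expect_equal(order(adj[adj < 1]), order(p[adj < 1]))
  expect_equal(bonferroni_adjust(p[1:7]),
               stats::p.adjust(p[1:7], "bonferroni"))
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
})

test_that("manipulation-check summaries are per condition and item", {
  tab <- data.frame(condition = rep(c("confirmation", "violation"),
                                    each = 2),
                    post_block1 = c(10, 20, 15, 25),
                    prediction_block2 = c(20, 30, 25, 35),
                    post_block2 = c(12, 18, 40, 50))
  s <- manipulation_check_summary(tab)
  expect_equal(nrow(s), 6)
  expect_equal(s$mean[s$condition == "confirmation" &
                        s$item == "post_block1"], 15)
  expect_equal(s$sd[s$condition == "confirmation" &
                      s$item == "post_block1"], sqrt(50), tolerance = 1e-9)
  expect_equal(round(sqrt(50), 3), 7.071)
  expect_error(manipulation_check_summary(tab[, 1:3]), "missing")
  expect_warning(manipulation_check_summary(tab[c(1, 3), ]),
                 "SD undefined")
})
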