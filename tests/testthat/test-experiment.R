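test_that("conditions carry the right staircase rules", {
  conds <- paradigm_conditions()
  expect_named(conds, c("confirmation", "violation", "violation_inhibiting",
                        "violation_enhancing"))
  for (c in conds) expect_equal(c$block1_rule$widen_ms, 3)
  expect_equal(conds$confirmation$block2_rule$shrink_ms, 12)  # hard stays
  for (lbl in c("violation", "violation_inhibiting", "violation_enhancing")) {
    expect_equal(conds[[lbl]]$block2_rule$widen_ms, 12)       # easy switch
  }
})

test_that("run_participant assembles the three phases with carry-over", {
  design <- experiment_design()
  p <- participant_params(1000, 100)
  rec <- run_participant(design, "violation", p, seed = 11)
  expect_equal(table(rec$trials$phase)[c("training", "block1", "block2")],
               table(factor(rep(c("training", "block1", "block2"),
                                c(20, 80, 80)),
                            levels = unique(rec$trials$phase)))[
                 c("training", "block1", "block2")])
  b1 <- rec$trials[rec$trials$phase == "block1", ]
  b2 <- rec$trials[rec$trials$phase == "block2", ]
  # block 1 resets to the initial window; block 2 continues from block 1
  expect_equal(c(b1$lower_before[1], b1$upper_before[1]), c(990, 1100))
  expect_equal(b2$lower_before[1], b1$lower_after[80])
  expect_equal(b2$upper_before[1], b1$upper_after[80])
  # stored accuracies recompute from the trials
  expect_equal(rec$accuracy_block1,
               100 * mean(b1$feedback[b1$scored] == "correct"))
  expect_equal(rec$accuracy_block2,
               100 * mean(b2$feedback[b2$scored] == "correct"))
  expect_equal(rec$accuracy_training,
               100 * mean(rec$trials$feedback[rec$trials$phase ==
                                                "training"] == "correct"))
  # deterministic given the seed
  rec2 <- run_participant(design, "violation", p, seed = 11)
  expect_identical(rec$trials, rec2$trials)
})

test_that("a zero-spread midpoint responder is perfect in every condition", {
  p <- participant_params(1045, 0, lapse_rate = 0)
  for (lbl in names(paradigm_conditions())) {
    rec <- run_participant(experiment_design(), lbl, p, seed = 1)
    expect_equal(rec$accuracy_block1, 100)
    expect_equal(rec$accuracy_block2, 100)
  }
})

test_that("easy block-2 feedback yields higher accuracy than hard", {
  p <- participant_params(950, 120, lapse_rate = 0.02)
  # oracle route
  ov <- predict_block_accuracy(p, "violation")
  oc <- predict_block_accuracy(p, "confirmation")
  expect_equal(ov$block1$expected_accuracy, oc$block1$expected_accuracy)
  expect_gt(ov$block2$expected_accuracy, oc$block2$expected_accuracy)
  # simulation route
  set.seed(12)
  sv <- simulate_condition_accuracy(p, "violation", experiment_design(),
                                    40, 5)
  sc <- simulate_condition_accuracy(p, "confirmation", experiment_design(),
                                    40, 5)
  expect_gt(mean(sv$mean_block2), mean(sc$mean_block2))
})

test_that("cohorts have the configured group sizes", {
  spec <- cohort_spec(n_per_condition = c(28, 28, 29, 28), master_seed = 5)
  tab <- draw_cohort(spec)
  expect_equal(nrow(tab), 113)
  expect_equal(as.vector(table(tab$condition)[c(
    "confirmation", "violation", "violation_inhibiting",
    "violation_enhancing")]), c(28, 28, 29, 28))
})

test_that("block-1 accuracy does not differ by condition", {
  # all conditions are identical until block 2: across replicate small
  # cohorts the rate of nominally significant one-way block-1 effects
  # stays near the alpha level
  design <- experiment_design(training_trials = 0, block_trials = 30)
  p <- participant_params(950, 120, lapse_rate = 0.02)
  set.seed(31)
  n_sig <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    accs <- unlist(lapply(names(paradigm_conditions()), function(lbl) {
      vapply(1:8, function(i) {
        run_participant(design, lbl, p, seed = sample.int(1e8, 1),
                        keep_trials = FALSE)$accuracy_block1
      }, 0)
    }))
    grp <- factor(rep(names(paradigm_conditions()), each = 8))
    pval <- summary(aov(accs ~ grp))[[1]]$`Pr(>F)`[1]
    if (pval < 0.05) n_sig <- n_sig + 1
  }
  # expected ~3 of 60 at alpha = .05; 12 is > 4 sd above that
  expect_lte(n_sig, 12)
})

test_that("the low-accuracy exclusion rule is applied and monotone", {
  mk <- function(id, tr, b1, b2) {
    structure(list(participant_id = id, condition = "violation",
                   params = participant_params(), seed = 1L, trials = NULL,
                   accuracy_training = tr, accuracy_block1 = b1,
                   accuracy_block2 = b2, excluded = FALSE,
                   exclusion_reason = NA_character_),
              class = "participant_record")
  }
  recs <- list(mk("A", 5.0, 4.8, 5.9),    # below 6 under any reading
               mk("B", 6.5, 10.0, 50.0),  # clearly retained
               mk("C", 2.0, 8.0, 9.0))    # mean 6.33: reading-dependent
  res <- apply_exclusions(recs, 6, reading = "mean")
  expect_equal(vapply(res$excluded, `[[`, "", "participant_id"), "A")
  expect_equal(length(res$retained) + length(res$excluded), length(recs))
  res_all <- apply_exclusions(recs, 6, reading = "all_blocks")
  expect_equal(vapply(res_all$excluded, `[[`, "", "participant_id"), "A")

  # monotonicity: raising the threshold never un-excludes anyone
  set.seed(44)
  for (r in 1:25) {
    recs <- lapply(1:12, function(i) {
      mk(sprintf("R%02d", i), runif(1, 0, 20), runif(1, 0, 20),
         runif(1, 0, 60))
    })
    prev <- character(0)
    for (thr in c(2, 6, 10, 15)) {
      now <- vapply(apply_exclusions(recs, thr)$excluded, `[[`, "",
                    "participant_id")
      expect_true(all(prev %in% now))
      prev <- now
    }
  }
})
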