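#' The four feedback conditions of the expectation paradigm
#'
#' Every condition runs the hard staircase in block 1 (negative expectation
#' induction). In block 2 the `confirmation` condition keeps the hard rule;
#' the `violation` condition and the two instruction conditions
#' (`violation_inhibiting`, `violation_enhancing`) switch to the easy rule.
#' The instruction conditions differ from plain `violation` only by label:
#' instructions have no computational mechanism here, so any behavioural
#' effect must be injected through the responder parameters.
#'
#' @param label One of `"confirmation"`, `"violation"`,
#'   `"violation_inhibiting"`, `"violation_enhancing"`.
#' @return `condition_spec()`: a `condition` object with `label`,
#'   `block1_rule` and `block2_rule`. `paradigm_conditions()`: the named
#'   list of all four.
#' @export
condition_spec <- function(label = c("confirmation", "violation",
                                     "violation_inhibiting",
                                     "violation_enhancing")) {
  label <- match.arg(label)
  structure(list(label = label,
                 block1_rule = rule_hard(),
                 block2_rule = if (label == "confirmation") rule_hard()
                               else rule_easy()),
            class = "condition")
}

#' @rdname condition_spec
#' @export
paradigm_conditions <- function() {
  labels <- c("confirmation", "violation", "violation_inhibiting",
              "violation_enhancing")
  stats::setNames(lapply(labels, condition_spec), labels)
}

#' Experiment design
#'
#' Block structure and window-handling policy of the paradigm: a 20-trial
#' training block, then two 80-trial experimental blocks. The tolerance
#' window starts at `[990, 1100]` ms; by default it is reset to that
#' initial window at the start of block 1 (training is practice only) and
#' carried over from block 1 into block 2, so the difficulty switch is
#' seamless and implicit. Stimulus timing (cue, feedback, inter-trial
#' interval) is carried as metadata only; no real-time presentation is
#' modelled.
#'
#' @param training_trials Trials in the training block.
#' @param block_trials Trials in each experimental block.
#' @param initial_window Starting [tolerance_window()].
#' @param training_rule [staircase_rule()] used during training.
#' @param carry_training_into_block1 Logical; if `TRUE` block 1 starts from
#'   training's final window instead of `initial_window`.
#' @param carry_block1_into_block2 Logical; if `TRUE` (default) block 2
#'   continues from block 1's final window.
#' @param timing Metadata list (cue, feedback and inter-trial durations).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(training_trials = 20, block_trials = 80,
                              initial_window = tolerance_window(990, 1100),
                              training_rule = rule_hard(),
                              carry_training_into_block1 = FALSE,
                              carry_block1_into_block2 = TRUE,
                              timing = list(cue_hz = 1000, cue_ms = 50,
                                            feedback_ms = 1000,
                                            iti_ms = c(1400, 1600))) {
  training_trials <- as.integer(training_trials)
  block_trials <- as.integer(block_trials)
  if (training_trials < 0L) stop("training_trials must be >= 0")
  if (block_trials < 1L) stop("block_trials must be >= 1")
  stopifnot(inherits(initial_window, "tolerance_window"),
            inherits(training_rule, "staircase_rule"))
  structure(list(training_trials = training_trials,
                 block_trials = block_trials,
                 initial_window = initial_window,
                 training_rule = training_rule,
                 carry_training_into_block1 =
                   isTRUE(carry_training_into_block1),
                 carry_block1_into_block2 = isTRUE(carry_block1_into_block2),
                 timing = timing),
            class = "experiment_design")
}

#' Run one participant through the full paradigm
#'
#' Training (unscored), block 1 under the hard rule, block 2 under the
#' condition's rule, with window resets/carry-over per the design. The
#' per-block accuracies are computed from the trials: training accuracy
#' over all training trials (needed by the exclusion rule), experimental
#' block accuracies over scored trials only (first trial dropped).
#'
#' @param design An [experiment_design()].
#' @param condition A [condition_spec()] or its label.
#' @param params A [participant_params()].
#' @param seed Integer seed for this participant's response stream.
#' @param participant_id Identifier stored in the record.
#' @param keep_trials If `FALSE`, drop the trial-level data from the record
#'   (accuracies are still computed); useful for large simulations.
#' @return A `participant_record`: list with `participant_id`, `condition`,
#'   `params`, `seed`, `trials` (data frame with a `phase` column, or
#'   `NULL`), `accuracy_training`, `accuracy_block1`, `accuracy_block2`,
#'   `excluded`, `exclusion_reason`.
#' @export
run_participant <- function(design, condition, params, seed,
                            participant_id = "P001", keep_trials = TRUE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "participant_params"))
  if (is.character(condition)) condition <- condition_spec(condition)
  stopifnot(inherits(condition, "condition"))
  set.seed(as.integer(seed))

  offset <- 0L
  training <- NULL
  if (design$training_trials > 0L) {
    training <- run_block(params, design$initial_window,
                          design$training_trials, design$training_rule,
                          score_policy = "training", trial_offset = offset)
    offset <- offset + design$training_trials
  }
  b1_start <- if (design$carry_training_into_block1 && !is.null(training)) {
    training$final_window
  } else {
    design$initial_window
  }
  block1 <- run_block(params, b1_start, design$block_trials,
                      condition$block1_rule, score_policy = "drop_first",
                      trial_offset = offset)
  offset <- offset + design$block_trials
  b2_start <- if (design$carry_block1_into_block2) block1$final_window
              else design$initial_window
  block2 <- run_block(params, b2_start, design$block_trials,
                      condition$block2_rule, score_policy = "drop_first",
                      trial_offset = offset)

  acc_training <- if (is.null(training)) NA_real_ else
    100 * mean(training$trials$feedback == "correct")
  trials <- NULL
  if (keep_trials) {
    pieces <- list()
    if (!is.null(training)) {
      pieces$training <- cbind(phase = "training", training$trials)
    }
    pieces$block1 <- cbind(phase = "block1", block1$trials)
    pieces$block2 <- cbind(phase = "block2", block2$trials)
    trials <- do.call(rbind, pieces)
    rownames(trials) <- NULL
  }
  structure(list(participant_id = participant_id,
                 condition = condition$label,
                 params = params,
                 seed = as.integer(seed),
                 trials = trials,
                 accuracy_training = acc_training,
                 accuracy_block1 = scored_accuracy(block1$trials),
                 accuracy_block2 = scored_accuracy(block2$trials),
                 excluded = FALSE,
                 exclusion_reason = NA_character_),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant %s [%s]: accuracy training %.1f%%, block1 %.1f%%, block2 %.1f%%%s>\n",
              x$participant_id, x$condition, x$accuracy_training,
              x$accuracy_block1, x$accuracy_block2,
              if (isTRUE(x$excluded)) " (excluded)" else ""))
  invisible(x)
}

#' Run a full cohort across conditions
#'
#' Draws responder models from the cohort spec and runs each participant
#' independently with their own child seed.
#'
#' @param design An [experiment_design()].
#' @param spec A [cohort_spec()].
#' @param conditions Character vector of condition labels.
#' @param keep_trials Passed to [run_participant()].
#' @return A list of `participant_record`s.
#' @export
run_cohort <- function(design, spec,
                       conditions = names(paradigm_conditions()),
                       keep_trials = TRUE) {
  tab <- draw_cohort(spec, conditions)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    params <- participant_params(row$mean_ms, row$sd_ms, row$lapse_rate,
                                 row$lapse_spread_ms, row$drift_ms_per_trial)
    run_participant(design, row$condition, params, row$seed,
                    participant_id = row$participant_id,
                    keep_trials = keep_trials)
  })
}

#' Apply the low-accuracy exclusion rule
#'
#' A participant is excluded when accuracy falls below `min_accuracy_pct`
#' "across all three blocks". Two readings are supported: `"mean"`
#' (default) excludes when the mean of training, block-1 and block-2
#' accuracies is below the threshold; `"all_blocks"` excludes only when
#' every one of the three is below it.
#'
#' @param records List of `participant_record`s.
#' @param min_accuracy_pct Exclusion threshold in percent (default 6).
#' @param reading `"mean"` or `"all_blocks"`.
#' @return A list with `retained` (records, `excluded = FALSE`),
#'   `excluded` (records flagged with a reason) and `log` (a data frame of
#'   id, condition, accuracies, reason).
#' @export
apply_exclusions <- function(records, min_accuracy_pct = 6,
                             reading = c("mean", "all_blocks")) {
  reading <- match.arg(reading)
  accs <- vapply(records, function(r) {
    c(r$accuracy_training, r$accuracy_block1, r$accuracy_block2)
  }, numeric(3))
  if (anyNA(accs)) stop("all records need training and block accuracies")
  out <- switch(reading,
                mean = colMeans(accs) < min_accuracy_pct,
                all_blocks = apply(accs < min_accuracy_pct, 2, all))
  log <- data.frame(
    participant_id = vapply(records, `[[`, "", "participant_id"),
    condition = vapply(records, `[[`, "", "condition"),
    accuracy_training = accs[1, ],
    accuracy_block1 = accs[2, ],
    accuracy_block2 = accs[3, ],
    excluded = out,
    reason = ifelse(out, sprintf("accuracy below %g%% (%s of three blocks)",
                                 min_accuracy_pct, reading), NA_character_),
    stringsAsFactors = FALSE
  )
  excluded <- lapply(which(out), function(i) {
    r <- records[[i]]
    r$excluded <- TRUE
    r$exclusion_reason <- log$reason[i]
    r
  })
  list(retained = records[!out], excluded = excluded, log = log)
}

#' Per-participant summary table
#'
#' @param records List of `participant_record`s.
#' @return Data frame with one row per participant: id, condition, the
#'   three accuracies, seed and exclusion flag.
#' @export
participant_summary <- function(records) {
  data.frame(
    participant_id = vapply(records, `[[`, "", "participant_id"),
    condition = vapply(records, `[[`, "", "condition"),
    accuracy_training = vapply(records, `[[`, 0, "accuracy_training"),
    accuracy_block1 = vapply(records, `[[`, 0, "accuracy_block1"),
    accuracy_block2 = vapply(records, `[[`, 0, "accuracy_block2"),
    seed = vapply(records, `[[`, 0L, "seed"),
    excluded = vapply(records, `[[`, FALSE, "excluded"),
    stringsAsFactors = FALSE
  )
}

#' Fast simulation of block accuracies for a homogeneous condition group
#'
#' Runs `n_cohorts` independent cohorts of `n_participants` identical
#' responders through the full design (training, block 1, block 2) using
#' the same trial-wise engine as [run_block()], vectorised across
#' participants. Used for replication-scale studies where trial-level
#' records are not needed.
#'
#' @param params A [participant_params()] shared by all participants.
#' @param condition A [condition_spec()] or label.
#' @param design An [experiment_design()].
#' @param n_participants Participants per cohort.
#' @param n_cohorts Number of replicate cohorts.
#' @return Data frame with one row per cohort: `cohort`, `mean_block1`,
#'   `mean_block2` (mean scored accuracy in percent).
#' @export
simulate_condition_accuracy <- function(params, condition, design,
                                        n_participants, n_cohorts = 1) {
  stopifnot(inherits(params, "participant_params"),
            inherits(design, "experiment_design"))
  if (is.character(condition)) condition <- condition_spec(condition)
  n <- as.integer(n_participants)
  draw <- function(n_trials, offset) {
    matrix(sample_responses(params,
                            rep(offset + seq_len(n_trials) - 1L, n)),
           nrow = n_trials)
  }
  res <- matrix(NA_real_, n_cohorts, 2)
  for (k in seq_len(n_cohorts)) {
    lower <- rep(design$initial_window$lower_ms, n)
    upper <- rep(design$initial_window$upper_ms, n)
    offset <- 0L
    if (design$training_trials > 0L) {
      tr <- .staircase_sweep(draw(design$training_trials, offset),
                             lower, upper, design$training_rule)
      offset <- offset + design$training_trials
      if (design$carry_training_into_block1) {
        lower <- tr$final_lower
        upper <- tr$final_upper
      }
    }
    b1 <- .staircase_sweep(draw(design$block_trials, offset), lower, upper,
                           condition$block1_rule)
    offset <- offset + design$block_trials
    if (design$carry_block1_into_block2) {
      lower <- b1$final_lower
      upper <- b1$final_upper
    } else {
      lower <- rep(design$initial_window$lower_ms, n)
      upper <- rep(design$initial_window$upper_ms, n)
    }
    b2 <- .staircase_sweep(draw(design$block_trials, offset), lower, upper,
                           condition$block2_rule)
    scored <- seq_len(design$block_trials) > 1L
    res[k, 1] <- 100 * mean(colMeans(b1$correct[scored, , drop = FALSE]))
    res[k, 2] <- 100 * mean(colMeans(b2$correct[scored, , drop = FALSE]))
  }
  data.frame(cohort = seq_len(n_cohorts),
             mean_block1 = res[, 1], mean_block2 = res[, 2])
}
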