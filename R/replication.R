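#' Replicate the published block-2 accuracy separation by simulation
#'
#' The full replication protocol for the paradigm's central behavioural
#' result: calibrate a shared responder model so the oracle-predicted
#' block-1 scored accuracy matches the published pooled block-1 mean
#' (about 16.5%), then simulate replicate cohorts of the violation
#' condition (hard staircase in block 1, easy staircase in block 2,
#' window carried over) and the confirmation condition (hard staircase in
#' both blocks) and report the grand mean block-2 scored accuracies and
#' their difference. The published values these are compared against are
#' 53.66% (violation), 16.46% (confirmation) and -37.21 percentage points
#' (confirmation minus violation).
#'
#' @param seed Integer seed for all randomness in the simulation.
#' @param n_cohorts Number of replicate cohorts per condition.
#' @param n_per_cohort Participants per cohort (28, the published group
#'   size).
#' @param target_block1_pct Calibration target; defaults to
#'   [reference_block1_target()].
#' @param design The [experiment_design()] to run.
#' @return A list: `params` (the calibrated [participant_params()]),
#'   `oracle` (oracle-predicted block accuracies per condition),
#'   `block1_violation`, `block1_confirmation`, `block2_violation`,
#'   `block2_confirmation` (grand means, percent),
#'   `block2_difference` (confirmation minus violation, percentage
#'   points), `n_cohorts`, `n_per_cohort`, and the per-cohort tables
#'   `cohorts_violation` / `cohorts_confirmation`.
#' @export
replicate_reference_study <- function(seed, n_cohorts = 200,
                                      n_per_cohort = 28,
                                      target_block1_pct =
                                        reference_block1_target(),
                                      design = experiment_design()) {
  set.seed(as.integer(seed))
  params <- calibrate_params(target_block1_pct)
  oracle <- list(
    violation = predict_block_accuracy(params, "violation", design),
    confirmation = predict_block_accuracy(params, "confirmation", design))
  sv <- simulate_condition_accuracy(params, "violation", design,
                                    n_per_cohort, n_cohorts)
  sc <- simulate_condition_accuracy(params, "confirmation", design,
                                    n_per_cohort, n_cohorts)
  list(params = params,
       oracle = oracle,
       block1_violation = mean(sv$mean_block1),
       block1_confirmation = mean(sc$mean_block1),
       block2_violation = mean(sv$mean_block2),
       block2_confirmation = mean(sc$mean_block2),
       block2_difference = mean(sc$mean_block2) - mean(sv$mean_block2),
       n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
       cohorts_violation = sv, cohorts_confirmation = sc)
}
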