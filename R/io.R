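#' @name csv_schemas
#' @title Versioned CSV interchange formats
#' @description
#' All desk-scale data exchange goes through plain CSV files whose first
#' line is a schema tag comment (`#timestair/<kind>/v1`). Readers refuse
#' unknown tags loudly so silent format drift is impossible.
#'
#' * trials: `participant_id, condition, phase, trial_index, scored,
#'   response_time_ms, lower_ms, upper_ms, feedback, seed` — one row per
#'   trial; `lower_ms`/`upper_ms` are the window the response was
#'   classified against; `feedback` is 1 for correct.
#' * participants: the per-participant summary of [participant_summary()].
#' * summary: the group summary of [summarize_cohort()].
NULL

.schema_tags <- c(trials = "#timestair/trials/v1",
                  participants = "#timestair/participants/v1",
                  summary = "#timestair/summary/v1")

.write_tagged_csv <- function(df, path, kind) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  con <- file(tmp, open = "w", encoding = "UTF-8")
  writeLines(.schema_tags[[kind]], con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

.read_tagged_csv <- function(path, kind) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!identical(first, .schema_tags[[kind]])) {
    stop(sprintf("'%s' does not carry schema tag %s (found: %s)",
                 path, .schema_tags[[kind]], first))
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read/write the trial-level CSV
#'
#' @param records List of `participant_record`s (with trials kept).
#' @param path File path.
#' @return `write_trials_csv()` returns the path invisibly;
#'   `read_trials_csv()` the trial data frame.
#' @export
write_trials_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (is.null(r$trials)) stop("record has no trial-level data")
    data.frame(participant_id = r$participant_id,
               condition = r$condition,
               phase = r$trials$phase,
               trial_index = r$trials$trial_index,
               scored = as.integer(r$trials$scored),
               response_time_ms = r$trials$response_time_ms,
               lower_ms = r$trials$lower_before,
               upper_ms = r$trials$upper_before,
               feedback = as.integer(r$trials$feedback == "correct"),
               seed = r$seed,
               stringsAsFactors = FALSE)
  })
  .write_tagged_csv(do.call(rbind, rows), path, "trials")
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) .read_tagged_csv(path, "trials")

#' Read/write the per-participant summary CSV
#'
#' @param summary Data frame from [participant_summary()].
#' @param path File path.
#' @export
write_participants_csv <- function(summary, path) {
  .write_tagged_csv(summary, path, "participants")
}

#' @rdname write_participants_csv
#' @export
read_participants_csv <- function(path) .read_tagged_csv(path, "participants")

#' Read/write the group summary CSV
#'
#' @param summary Data frame from [summarize_cohort()].
#' @param path File path.
#' @export
write_summary_csv <- function(summary, path) {
  .write_tagged_csv(summary, path, "summary")
}

#' @rdname write_participants_csv
#' @export
read_summary_csv <- function(path) .read_tagged_csv(path, "summary")

#' Default run configuration
#'
#' The canonical declarative description of a simulation run: design
#' (trial counts, initial window, carry-over flags), conditions, cohort
#' spec and master seed. Serialized to/from YAML; the round trip is
#' lossless on this canonical form.
#'
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    design = list(training_trials = 20L, block_trials = 80L,
                  initial_window = c(990, 1100),
                  carry_training_into_block1 = FALSE,
                  carry_block1_into_block2 = TRUE),
    conditions = c("confirmation", "violation", "violation_inhibiting",
                   "violation_enhancing"),
    cohort = list(n_per_condition = c(28L, 28L, 29L, 28L),
                  mean_ms = 1000, sd_ms = 100, lapse_rate = 0.02,
                  lapse_spread_ms = 1000, drift_ms_per_trial = 0,
                  master_seed = 1L)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A list as in [default_run_config()].
#' @return The validated config (class `run_config`), invisibly usable.
#' @export
validate_run_config <- function(config) {
  need <- function(x, key, parent = NULL) {
    if (is.null(x)) {
      stop(sprintf("config key missing: %s%s",
                   if (is.null(parent)) "" else paste0(parent, "."), key))
    }
    x
  }
  design <- need(config$design, "design")
  for (k in c("training_trials", "block_trials", "initial_window",
              "carry_training_into_block1", "carry_block1_into_block2")) {
    need(design[[k]], k, "design")
  }
  if (length(design$initial_window) != 2L ||
      design$initial_window[1] > design$initial_window[2]) {
    stop("config key invalid: design.initial_window must be c(lower, upper)")
  }
  need(config$conditions, "conditions")
  bad <- setdiff(config$conditions,
                 c("confirmation", "violation", "violation_inhibiting",
                   "violation_enhancing"))
  if (length(bad)) {
    stop("config key invalid: conditions contains unknown label(s): ",
         paste(bad, collapse = ", "))
  }
  cohort <- need(config$cohort, "cohort")
  for (k in c("n_per_condition", "mean_ms", "sd_ms", "lapse_rate",
              "lapse_spread_ms", "drift_ms_per_trial", "master_seed")) {
    need(cohort[[k]], k, "cohort")
  }
  class(config) <- "run_config"
  config
}

#' Read/write a run configuration file (YAML)
#'
#' @param path File path.
#' @param config A run configuration list.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  # yaml scalars come back untyped lists at times; normalize vectors
  config$design$initial_window <- as.numeric(unlist(config$design$initial_window))
  config$conditions <- as.character(unlist(config$conditions))
  config$cohort$n_per_condition <-
    as.integer(unlist(config$cohort$n_per_condition))
  validate_run_config(config)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_to_objects <- function(config) {
  design <- experiment_design(
    training_trials = config$design$training_trials,
    block_trials = config$design$block_trials,
    initial_window = tolerance_window(config$design$initial_window[1],
                                      config$design$initial_window[2]),
    carry_training_into_block1 = config$design$carry_training_into_block1,
    carry_block1_into_block2 = config$design$carry_block1_into_block2)
  spec <- cohort_spec(
    n_per_condition = config$cohort$n_per_condition,
    mean_ms = config$cohort$mean_ms, sd_ms = config$cohort$sd_ms,
    lapse_rate = config$cohort$lapse_rate,
    lapse_spread_ms = config$cohort$lapse_spread_ms,
    drift_ms_per_trial = config$cohort$drift_ms_per_trial,
    master_seed = config$cohort$master_seed)
  list(design = design, spec = spec, conditions = config$conditions)
}

#' Simulate a full experiment from a configuration
#'
#' Runs the configured cohort and writes `trials.csv`,
#' `participants.csv` and a `manifest.yaml` (config hash, seed, package
#' version) into `out_dir`. Files are written atomically and the run is
#' byte-identical on rerun with the same configuration.
#'
#' @param config Path to a YAML config file or a run-config list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's master seed.
#' @param quiet Suppress the progress message.
#' @return Invisibly, a list with the records, the retained/excluded split
#'   and the output paths.
#' @export
cli_simulate <- function(config = default_run_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- read_run_config(config)
  } else {
    config <- validate_run_config(config)
  }
  if (!is.null(seed)) config$cohort$master_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  objs <- .config_to_objects(config)
  records <- run_cohort(objs$design, objs$spec, objs$conditions)
  split <- apply_exclusions(records)
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                participants = file.path(out_dir, "participants.csv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_trials_csv(records, paths$trials)
  write_participants_csv(participant_summary(c(split$retained,
                                               split$excluded)),
                         paths$participants)
  if (is.null(config_path)) {
    config_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, config_path)
  }
  manifest <- list(config_md5 = unname(tools::md5sum(config_path)),
                   master_seed = config$cohort$master_seed,
                   n_participants = length(records),
                   n_excluded = length(split$excluded),
                   package_version =
                     as.character(utils::packageVersion("timestair")))
  yaml::write_yaml(manifest, paths$manifest)
  if (!quiet) {
    message(sprintf("simulated %d participants (%d excluded) -> %s",
                    length(records), length(split$excluded), out_dir))
  }
  invisible(list(records = records, retained = split$retained,
                 excluded = split$excluded, paths = paths))
}

.default_contrast_pairs <- function(conditions) {
  std <- c("confirmation", "violation", "violation_inhibiting",
           "violation_enhancing")
  if (all(std %in% conditions)) {
    cbind("confirmation", setdiff(std, "confirmation"))
  } else {
    t(utils::combn(sort(conditions), 2))
  }
}

#' Analyse simulated or recorded accuracy data
#'
#' Accepts a trial-level CSV, a per-participant summary CSV, or a group
#' summary CSV (detected by schema tag), and writes `summary.csv`,
#' `contrasts.csv` and, when per-participant data are available,
#' `anova.csv` into `out_dir`. Contrasts cover each standard pair both for
#' block 2 and marginally over the two blocks; with summary-only input
#' the CI and p fields stay empty.
#'
#' @param in_file Input CSV path.
#' @param out_dir Output directory.
#' @param summary_only Treat the input as a group summary even if richer.
#' @param quiet Suppress the progress message.
#' @return Invisibly, a list with `summary`, `contrasts` and `anova`.
#' @export
cli_analyze <- function(in_file, out_dir, summary_only = FALSE,
                        quiet = FALSE) {
  first <- readLines(in_file, n = 1L, encoding = "UTF-8")
  kind <- names(.schema_tags)[match(first, .schema_tags)]
  if (is.na(kind)) {
    stop(sprintf("'%s' carries no known schema tag (line 1: %s)",
                 in_file, first))
  }
  data <- NULL
  if (kind == "trials") {
    trials <- read_trials_csv(in_file)
    data <- .trials_to_participants(trials)
  } else if (kind == "participants") {
    data <- read_participants_csv(in_file)
  }
  if (!is.null(data) && "excluded" %in% names(data)) {
    data <- data[!as.logical(data$excluded), , drop = FALSE]
  }
  if (summary_only) data <- NULL
  summary <- if (is.null(data)) read_summary_csv(in_file)
             else summarize_cohort(data)

  pairs <- .default_contrast_pairs(unique(summary$condition))
  contrasts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    rbind(posthoc_mean_difference(summary, pairs[i, 1], pairs[i, 2],
                                  block = "block2", data = data),
          marginal_mean_difference(summary, pairs[i, 1], pairs[i, 2],
                                   data = data))
  }))
  anova_tab <- NULL
  if (!is.null(data) && all(table(data$condition) >= 2)) {
    fit <- mixed_anova(data)
    anova_tab <- fit$anova
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_csv(summary, file.path(out_dir, "summary.csv"))
  utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  if (!is.null(anova_tab)) {
    utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
  }
  if (!quiet) {
    message(sprintf("analysis of %s (%s input) -> %s", in_file, kind,
                    out_dir))
  }
  invisible(list(summary = summary, contrasts = contrasts,
                 anova = anova_tab))
}

# aggregate a trial table back into per-participant accuracies
.trials_to_participants <- function(trials) {
  acc <- function(g, phase, scored_only) {
    rows <- g[g$phase == phase & (!scored_only | g$scored == 1L), ]
    if (!nrow(rows)) return(NA_real_)
    100 * mean(rows$feedback == 1L)
  }
  out <- do.call(rbind, lapply(split(trials, trials$participant_id),
                               function(g) {
    data.frame(participant_id = g$participant_id[1],
               condition = g$condition[1],
               accuracy_training = acc(g, "training", FALSE),
               accuracy_block1 = acc(g, "block1", TRUE),
               accuracy_block2 = acc(g, "block2", TRUE),
               seed = g$seed[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tiny deterministic test cohort
#'
#' Four conditions x three participants with 5-trial training and 5-trial
#' experimental blocks — small enough to recount by hand. The last
#' participant of the `violation_enhancing` group responds several seconds
#' off target and therefore trips the low-accuracy exclusion rule.
#'
#' @param seed Integer seed.
#' @return A list with `design`, `records`, `summary` (per participant)
#'   and `exclusions` (the [apply_exclusions()] result).
#' @export
make_fixture <- function(seed = 42) {
  design <- experiment_design(training_trials = 5, block_trials = 5)
  tab <- draw_cohort(cohort_spec(n_per_condition = 3, mean_ms = 1045,
                                 sd_ms = 80, lapse_rate = 0,
                                 master_seed = seed))
  tab$mean_ms[nrow(tab)] <- 5000  # hopeless responder -> excluded
  records <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    run_participant(design, row$condition,
                    participant_params(row$mean_ms, row$sd_ms,
                                       row$lapse_rate, row$lapse_spread_ms,
                                       row$drift_ms_per_trial),
                    row$seed, participant_id = row$participant_id)
  })
  list(design = design, records = records,
       summary = participant_summary(records),
       exclusions = apply_exclusions(records))
}
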