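#' Generative model of one synthetic responder
#'
#' Interval reproductions around the 1-s target are modelled as a mixture:
#' with probability `1 - lapse_rate` a draw from a normal law with mean
#' `mean_ms + trial_number * drift_ms_per_trial` and spread `sd_ms`
#' (scalar-timing noise); with probability `lapse_rate` an off-task lapse
#' with the same centre but spread `lapse_spread_ms`. Either component is
#' truncated to strictly positive times.
#'
#' @param mean_ms Central tendency of the produced interval (ms); > 0.
#' @param sd_ms Response spread (ms); >= 0.
#' @param lapse_rate Per-trial probability of an off-task response, in
#'   `[0, 1)`.
#' @param lapse_spread_ms Spread of lapse responses (ms).
#' @param drift_ms_per_trial Optional linear drift of the mean (ms/trial).
#' @return An object of class `participant_params`.
#' @examples
#' participant_params(mean_ms = 1000, sd_ms = 100)
#' @export
participant_params <- function(mean_ms = 1000, sd_ms = 100,
                               lapse_rate = 0.02, lapse_spread_ms = 1000,
                               drift_ms_per_trial = 0) {
  mean_ms <- as.numeric(mean_ms)
  sd_ms <- as.numeric(sd_ms)
  lapse_rate <- as.numeric(lapse_rate)
  lapse_spread_ms <- as.numeric(lapse_spread_ms)
  drift_ms_per_trial <- as.numeric(drift_ms_per_trial)
  if (!is.finite(mean_ms) || mean_ms <= 0) stop("mean_ms must be > 0")
  if (!is.finite(sd_ms) || sd_ms < 0) stop("sd_ms must be >= 0")
  if (!is.finite(lapse_rate) || lapse_rate < 0 || lapse_rate >= 1) {
    stop("lapse_rate must lie in [0, 1)")
  }
  if (!is.finite(lapse_spread_ms) || lapse_spread_ms < 0) {
    stop("lapse_spread_ms must be >= 0")
  }
  if (!is.finite(drift_ms_per_trial)) stop("drift_ms_per_trial must be finite")
  structure(list(mean_ms = mean_ms, sd_ms = sd_ms, lapse_rate = lapse_rate,
                 lapse_spread_ms = lapse_spread_ms,
                 drift_ms_per_trial = drift_ms_per_trial),
            class = "participant_params")
}

#' @export
print.participant_params <- function(x, ...) {
  cat(sprintf("<responder: mean %g ms, sd %g ms, lapse %g (spread %g ms), drift %g ms/trial>\n",
              x$mean_ms, x$sd_ms, x$lapse_rate, x$lapse_spread_ms,
              x$drift_ms_per_trial))
  invisible(x)
}

#' Draw interval-reproduction responses
#'
#' `sample_responses()` draws one response per entry of `trial_numbers`
#' from the mixture model in [participant_params()]; `sample_response()`
#' is the single-trial convenience wrapper. Draws are truncated to be
#' strictly positive by resampling the offending component.
#'
#' @param params A [participant_params()].
#' @param trial_numbers Integer vector of 0-based session trial ordinals
#'   (only used through the drift term).
#' @param trial_number Single 0-based trial ordinal.
#' @return Response time(s) in ms, strictly positive.
#' @export
sample_responses <- function(params, trial_numbers) {
  stopifnot(inherits(params, "participant_params"))
  n <- length(trial_numbers)
  mu <- params$mean_ms + as.numeric(trial_numbers) * params$drift_ms_per_trial
  is_lapse <- stats::runif(n) < params$lapse_rate
  sdv <- ifelse(is_lapse, params$lapse_spread_ms, params$sd_ms)
  x <- stats::rnorm(n, mu, sdv)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sdv[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' @rdname sample_responses
#' @export
sample_response <- function(params, trial_number = 0) {
  stopifnot(length(trial_number) == 1L)
  sample_responses(params, trial_number)
}

#' Cohort parameter specification
#'
#' Describes how to draw a cohort of responder models: for each field of
#' [participant_params()] either a fixed value (length 1) or an interval
#' (length 2) to sample uniformly per participant. `n_per_condition` may be
#' a single count or one count per condition (e.g. `c(28, 28, 29, 28)`).
#'
#' @param n_per_condition Count(s) of participants per condition; >= 1.
#' @param mean_ms,sd_ms,lapse_rate,lapse_spread_ms,drift_ms_per_trial Fixed
#'   value or `c(min, max)` interval for the corresponding responder field.
#' @param master_seed Integer seed from which per-participant seeds and
#'   parameter draws derive deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition, mean_ms = 1000, sd_ms = 100,
                        lapse_rate = 0.02, lapse_spread_ms = 1000,
                        drift_ms_per_trial = 0, master_seed = 1L) {
  n_per_condition <- as.integer(n_per_condition)
  if (any(is.na(n_per_condition)) || any(n_per_condition < 1L)) {
    stop("n_per_condition must be >= 1")
  }
  chk <- function(x, nm) {
    if (!length(x) %in% 1:2 || any(!is.finite(x))) {
      stop(sprintf("%s must be a fixed value or a length-2 interval", nm))
    }
    as.numeric(x)
  }
  structure(list(n_per_condition = n_per_condition,
                 mean_ms = chk(mean_ms, "mean_ms"),
                 sd_ms = chk(sd_ms, "sd_ms"),
                 lapse_rate = chk(lapse_rate, "lapse_rate"),
                 lapse_spread_ms = chk(lapse_spread_ms, "lapse_spread_ms"),
                 drift_ms_per_trial = chk(drift_ms_per_trial,
                                          "drift_ms_per_trial"),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

.draw_field <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else stats::runif(n, x[1], x[2])
}

#' Draw a cohort of responder parameter sets
#'
#' Reproducible from `master_seed`: the master seed drives the parameter
#' draws and a deterministic per-participant child seed, so any participant
#' can be re-run in isolation.
#'
#' @param spec A [cohort_spec()].
#' @param conditions Character vector of condition labels (one group each).
#' @return A data frame with one row per participant: `participant_id`,
#'   `condition`, the five responder fields, and `seed`.
#' @export
draw_cohort <- function(spec,
                        conditions = names(paradigm_conditions())) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_cond <- length(conditions)
  n_per <- rep_len(spec$n_per_condition, n_cond)
  total <- sum(n_per)
  set.seed(spec$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(total)),
    condition = rep(conditions, times = n_per),
    mean_ms = .draw_field(spec$mean_ms, total),
    sd_ms = .draw_field(spec$sd_ms, total),
    lapse_rate = .draw_field(spec$lapse_rate, total),
    lapse_spread_ms = .draw_field(spec$lapse_spread_ms, total),
    drift_ms_per_trial = .draw_field(spec$drift_ms_per_trial, total),
    seed = seeds,
    stringsAsFactors = FALSE
  )
}
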