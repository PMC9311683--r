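#' Tolerance window
#'
#' The staircase's state: the closed interval of response times (ms) that
#' earn "correct" feedback. The window may have zero width after repeated
#' shrinking, but the lower boundary never exceeds the upper one.
#'
#' @param lower_ms Lower boundary in milliseconds.
#' @param upper_ms Upper boundary in milliseconds.
#' @return An object of class `tolerance_window` with elements `lower_ms`
#'   and `upper_ms`.
#' @examples
#' tolerance_window(990, 1100)
#' @export
tolerance_window <- function(lower_ms, upper_ms) {
  lower_ms <- as.numeric(lower_ms)
  upper_ms <- as.numeric(upper_ms)
  if (length(lower_ms) != 1L || length(upper_ms) != 1L ||
      !is.finite(lower_ms) || !is.finite(upper_ms)) {
    stop("window boundaries must be single finite numbers (ms)")
  }
  if (lower_ms > upper_ms) {
    stop("lower_ms must not exceed upper_ms")
  }
  structure(list(lower_ms = lower_ms, upper_ms = upper_ms),
            class = "tolerance_window")
}

#' @export
print.tolerance_window <- function(x, ...) {
  cat(sprintf("<tolerance window [%g, %g] ms, width %g>\n",
              x$lower_ms, x$upper_ms, window_width(x)))
  invisible(x)
}

#' Width and midpoint of a tolerance window
#'
#' @param window A [tolerance_window()].
#' @return Width (ms) or midpoint (ms) as a single number.
#' @export
window_width <- function(window) window$upper_ms - window$lower_ms

#' @rdname window_width
#' @export
window_midpoint <- function(window) (window$lower_ms + window$upper_ms) / 2

#' Staircase update rule
#'
#' A weighted up/down rule: after incorrect feedback the window is widened
#' by `widen_ms` in total, after correct feedback it is shrunk by
#' `shrink_ms` in total, each split symmetrically over the two boundaries.
#' The long-run hit rate such a rule drives performance towards is
#' `widen_ms / (widen_ms + shrink_ms)` (see [equilibrium_hit_rate()]).
#'
#' `rule_hard()` (widen 3, shrink 12) keeps accuracy near 20%;
#' `rule_easy()` (widen 12, shrink 3) drives it towards 80%.
#'
#' @param widen_ms Total widening (ms) applied on incorrect feedback; > 0.
#' @param shrink_ms Total shrinking (ms) applied on correct feedback; > 0.
#' @param split Boundary-allocation policy; only `"symmetric"` (half of the
#'   step at each boundary) is defined.
#' @return An object of class `staircase_rule`.
#' @export
staircase_rule <- function(widen_ms, shrink_ms, split = "symmetric") {
  widen_ms <- as.numeric(widen_ms)
  shrink_ms <- as.numeric(shrink_ms)
  if (!is.finite(widen_ms) || widen_ms <= 0 ||
      !is.finite(shrink_ms) || shrink_ms <= 0) {
    stop("widen_ms and shrink_ms must be positive finite step sizes (ms)")
  }
  split <- match.arg(split, "symmetric")
  structure(list(widen_ms = widen_ms, shrink_ms = shrink_ms, split = split),
            class = "staircase_rule")
}

#' @rdname staircase_rule
#' @export
rule_hard <- function() staircase_rule(widen_ms = 3, shrink_ms = 12)

#' @rdname staircase_rule
#' @export
rule_easy <- function() staircase_rule(widen_ms = 12, shrink_ms = 3)

#' @export
print.staircase_rule <- function(x, ...) {
  cat(sprintf("<staircase rule: widen %g ms / shrink %g ms (%s split); equilibrium hit rate %.2f>\n",
              x$widen_ms, x$shrink_ms, x$split,
              x$widen_ms / (x$widen_ms + x$shrink_ms)))
  invisible(x)
}

#' Classify a response against the tolerance window
#'
#' Feedback is "correct" iff the response time lies inside the closed
#' interval `[lower_ms, upper_ms]`; boundary hits count as correct, which
#' also makes the zero-width degenerate window well defined. Pure function:
#' the window is not modified.
#'
#' @param response_time_ms Response time in ms; must be finite and positive.
#' @param window A [tolerance_window()].
#' @return `"correct"` or `"incorrect"`.
#' @examples
#' classify_response(1050, tolerance_window(990, 1100))
#' @export
classify_response <- function(response_time_ms, window) {
  response_time_ms <- as.numeric(response_time_ms)
  if (length(response_time_ms) != 1L || !is.finite(response_time_ms) ||
      response_time_ms <= 0) {
    stop("response_time_ms must be a single finite positive time (ms)")
  }
  stopifnot(inherits(window, "tolerance_window"))
  if (response_time_ms >= window$lower_ms && response_time_ms <= window$upper_ms) {
    "correct"
  } else {
    "incorrect"
  }
}

#' Apply one staircase update to the window
#'
#' On correct feedback both boundaries move inwards by `shrink_ms / 2`; on
#' incorrect feedback both move outwards by `widen_ms / 2`. If shrinking
#' would make the boundaries cross, both clamp to the window midpoint
#' (width zero). Every non-clamped update preserves the midpoint, and the
#' clamped one does too.
#'
#' @param window A [tolerance_window()].
#' @param feedback `"correct"` or `"incorrect"`.
#' @param rule A [staircase_rule()].
#' @return The updated [tolerance_window()].
#' @examples
#' apply_update(tolerance_window(990, 1100), "correct", rule_hard())
#' @export
apply_update <- function(window, feedback, rule) {
  stopifnot(inherits(window, "tolerance_window"),
            inherits(rule, "staircase_rule"))
  feedback <- match.arg(feedback, c("correct", "incorrect"))
  if (feedback == "correct") {
    lower <- window$lower_ms + rule$shrink_ms / 2
    upper <- window$upper_ms - rule$shrink_ms / 2
    if (lower > upper) {
      mid <- window_midpoint(window)
      lower <- mid
      upper <- mid
    }
  } else {
    lower <- window$lower_ms - rule$widen_ms / 2
    upper <- window$upper_ms + rule$widen_ms / 2
  }
  tolerance_window(lower, upper)
}

# Core vectorised sweep shared by every simulation path in the package.
# `responses` is an n_trials x P matrix of response times; `lower`/`upper`
# are length-P start boundaries. Applies classify + update trial by trial.
# With trace = TRUE also returns the pre-trial boundaries per trial.
.staircase_sweep <- function(responses, lower, upper, rule, trace = FALSE) {
  responses <- as.matrix(responses)
  n_trials <- nrow(responses)
  p <- ncol(responses)
  lower <- rep_len(as.numeric(lower), p)
  upper <- rep_len(as.numeric(upper), p)
  half_w <- rule$widen_ms / 2
  half_s <- rule$shrink_ms / 2
  correct <- matrix(FALSE, n_trials, p)
  if (trace) {
    lower_before <- matrix(NA_real_, n_trials, p)
    upper_before <- matrix(NA_real_, n_trials, p)
  }
  for (t in seq_len(n_trials)) {
    if (trace) {
      lower_before[t, ] <- lower
      upper_before[t, ] <- upper
    }
    r <- responses[t, ]
    hit <- r >= lower & r <= upper
    correct[t, ] <- hit
    step <- ifelse(hit, half_s, -half_w)
    lower <- lower + step
    upper <- upper - step
    crossed <- which(lower > upper)
    if (length(crossed)) {
      mid <- (lower[crossed] + upper[crossed]) / 2
      lower[crossed] <- mid
      upper[crossed] <- mid
    }
  }
  out <- list(correct = correct, final_lower = lower, final_upper = upper)
  if (trace) {
    out$lower_before <- lower_before
    out$upper_before <- upper_before
  }
  out
}

#' Run one block of staircase trials for a synthetic responder
#'
#' Draws a response for every trial from the participant model, classifies
#' it against the current window, and threads the window through
#' [apply_update()] after every trial. The scoring policy reflects the
#' paradigm's conventions: `"drop_first"` marks every trial except the
#' block's first as scored (the convention for the experimental blocks),
#' `"training"` marks none, `"all"` marks all.
#'
#' @param params A [participant_params()] responder model.
#' @param start_window The [tolerance_window()] at block start.
#' @param n_trials Number of trials (>= 1).
#' @param rule The [staircase_rule()] in force for this block.
#' @param score_policy `"drop_first"`, `"training"` or `"all"`.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   block is reproducible in isolation. If `NULL` the current RNG stream is
#'   used (the per-participant runner seeds once per participant).
#' @param trial_offset Ordinal of the first trial within the session
#'   (0-based); only relevant when the responder drifts.
#' @return A list with `trials` (a data frame with one row per trial:
#'   `trial_index`, `response_time_ms`, `feedback`, `lower_before`,
#'   `upper_before`, `lower_after`, `upper_after`, `scored`) and
#'   `final_window`, the [tolerance_window()] to carry into the next block.
#' @export
run_block <- function(params, start_window, n_trials, rule,
                      score_policy = c("drop_first", "training", "all"),
                      seed = NULL, trial_offset = 0) {
  stopifnot(inherits(params, "participant_params"),
            inherits(start_window, "tolerance_window"),
            inherits(rule, "staircase_rule"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  score_policy <- match.arg(score_policy)
  if (!is.null(seed)) set.seed(seed)

  trial_numbers <- trial_offset + seq_len(n_trials) - 1L
  responses <- sample_responses(params, trial_numbers)
  swept <- .staircase_sweep(matrix(responses, ncol = 1),
                            start_window$lower_ms, start_window$upper_ms,
                            rule, trace = TRUE)
  correct <- swept$correct[, 1]
  lower_before <- swept$lower_before[, 1]
  upper_before <- swept$upper_before[, 1]
  # reconstruct post-trial boundaries: next trial's pre-trial state
  lower_after <- c(lower_before[-1], swept$final_lower)
  upper_after <- c(upper_before[-1], swept$final_upper)

  scored <- switch(score_policy,
                   drop_first = seq_len(n_trials) > 1L,
                   training = rep(FALSE, n_trials),
                   all = rep(TRUE, n_trials))
  trials <- data.frame(
    trial_index = seq_len(n_trials) - 1L,
    response_time_ms = responses,
    feedback = ifelse(correct, "correct", "incorrect"),
    lower_before = lower_before,
    upper_before = upper_before,
    lower_after = lower_after,
    upper_after = upper_after,
    scored = scored,
    stringsAsFactors = FALSE
  )
  list(trials = trials,
       final_window = tolerance_window(swept$final_lower, swept$final_upper))
}

#' Percentage of correct feedback among scored trials
#'
#' @param trials A trial data frame as returned by [run_block()] (columns
#'   `feedback` and `scored`).
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
scored_accuracy <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("feedback", "scored") %in% names(trials)))
  keep <- as.logical(trials$scored)
  if (!any(keep)) stop("no scored trials: accuracy is undefined")
  100 * mean(trials$feedback[keep] == "correct")
}
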