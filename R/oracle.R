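#' Closed-form hit probability of a responder in a window
#'
#' Probability that one response from the mixture model lands inside the
#' closed tolerance window. Each mixture component is a normal law
#' truncated to positive times, exactly matching [sample_responses()]:
#' `P = (1 - lapse) * T(mean, sd) + lapse * T(mean, lapse_spread)` where
#' `T(m, s) = [Phi((u - m)/s) - Phi((max(l, 0) - m)/s)] / [1 - Phi(-m/s)]`.
#' A zero-spread component degenerates to a point mass (indicator of
#' membership in the closed interval).
#'
#' @param params A [participant_params()].
#' @param window A [tolerance_window()].
#' @param trial_number 0-based session trial ordinal; shifts the mean by
#'   the drift term.
#' @return A probability in `[0, 1]`.
#' @examples
#' hit_probability(participant_params(1000, 100, lapse_rate = 0),
#'                 tolerance_window(990, 1100))
#' @export
hit_probability <- function(params, window, trial_number = 0) {
  stopifnot(inherits(params, "participant_params"),
            inherits(window, "tolerance_window"))
  mu <- params$mean_ms + trial_number * params$drift_ms_per_trial
  comp <- function(s) {
    .trunc_normal_mass(window$lower_ms, window$upper_ms, mu, s)
  }
  (1 - params$lapse_rate) * comp(params$sd_ms) +
    params$lapse_rate * comp(params$lapse_spread_ms)
}

# mass of N(mu, s) truncated to (0, Inf) inside the closed interval [l, u];
# vectorised over l, u and mu
.trunc_normal_mass <- function(l, u, mu, s) {
  if (s == 0) {
    return(as.numeric(mu >= l & mu <= u & mu > 0))
  }
  lo <- pmax(l, 0)
  raw <- stats::pnorm(u, mu, s) - stats::pnorm(lo, mu, s)
  raw <- pmax(raw, 0)
  raw / stats::pnorm(0, mu, s, lower.tail = FALSE)
}

#' Equilibrium hit rate of a weighted up/down rule
#'
#' The hit rate at which the expected window-width change is zero:
#' a hit shrinks the width by `shrink_ms`, a miss widens it by `widen_ms`,
#' so `p * shrink = (1 - p) * widen` gives
#' `p = widen / (widen + shrink)` — 0.20 for the hard rule (3, 12) and
#' 0.80 for the easy rule (12, 3), independent of the responder.
#'
#' @param rule A [staircase_rule()].
#' @return The equilibrium probability.
#' @export
equilibrium_hit_rate <- function(rule) {
  stopifnot(inherits(rule, "staircase_rule"))
  rule$widen_ms / (rule$widen_ms + rule$shrink_ms)
}

#' Exact forward propagation of the staircase's accuracy dynamics
#'
#' Propagates the full probability distribution over reachable tolerance
#' windows trial by trial: each window state branches into its
#' hit-updated and miss-updated children (via the same update rule as
#' [apply_update()]) with weights given by [hit_probability()]. Because
#' the update is deterministic given the feedback, the set of reachable
#' windows lies on a small lattice and the pass is exact up to the pruning
#' of negligible mass. This is the independent oracle for the Monte-Carlo
#' simulator and the engine behind [calibrate_params()].
#'
#' @param params A [participant_params()].
#' @param rule A [staircase_rule()].
#' @param n_trials Number of trials to propagate (>= 1).
#' @param start_window Starting [tolerance_window()]; ignored when
#'   `start_distribution` is given.
#' @param start_distribution Optional state distribution (the
#'   `final_distribution` of a previous call) to chain blocks.
#' @param score_policy Which trials enter the expected accuracy:
#'   `"drop_first"` (default), `"all"` or `"training"` (none).
#' @param trial_offset 0-based session ordinal of the first trial (drift).
#' @param prune States with mass below this are dropped (and the dropped
#'   mass reported).
#' @param max_states Hard cap on the state-space size; exceeding it is an
#'   error suggesting coarser pruning.
#' @return A list: `trajectory` (expected hit probability per trial),
#'   `expected_accuracy` (mean over scored trials, in percent),
#'   `final_distribution` (list of `lower`, `upper`, `mass`), and
#'   `pruned_loss` (total probability mass dropped).
#' @export
forward_accuracy_trajectory <- function(params, rule, n_trials,
                                        start_window = tolerance_window(990, 1100),
                                        start_distribution = NULL,
                                        score_policy = c("drop_first", "all",
                                                         "training"),
                                        trial_offset = 0,
                                        prune = 1e-12, max_states = 1e6) {
  stopifnot(inherits(params, "participant_params"),
            inherits(rule, "staircase_rule"))
  score_policy <- match.arg(score_policy)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1")

  if (is.null(start_distribution)) {
    lower <- start_window$lower_ms
    upper <- start_window$upper_ms
    mass <- 1
  } else {
    lower <- start_distribution$lower
    upper <- start_distribution$upper
    mass <- start_distribution$mass
  }
  half_w <- rule$widen_ms / 2
  half_s <- rule$shrink_ms / 2
  lapse <- params$lapse_rate
  traj <- numeric(n_trials)
  pruned_loss <- 0

  for (t in seq_len(n_trials)) {
    mu <- params$mean_ms +
      (trial_offset + t - 1) * params$drift_ms_per_trial
    ph <- (1 - lapse) *
      .trunc_normal_mass(lower, upper, mu, params$sd_ms) +
      lapse * .trunc_normal_mass(lower, upper, mu, params$lapse_spread_ms)
    traj[t] <- sum(mass * ph)

    hit_l <- lower + half_s
    hit_u <- upper - half_s
    crossed <- hit_l > hit_u
    if (any(crossed)) {
      mid <- (lower[crossed] + upper[crossed]) / 2
      hit_l[crossed] <- mid
      hit_u[crossed] <- mid
    }
    new_l <- c(hit_l, lower - half_w)
    new_u <- c(hit_u, upper + half_w)
    new_m <- c(mass * ph, mass * (1 - ph))

    key <- paste(round(new_l, 6), round(new_u, 6))
    agg <- rowsum(new_m, key, reorder = FALSE)
    idx <- match(rownames(agg), key)
    lower <- new_l[idx]
    upper <- new_u[idx]
    mass <- agg[, 1]

    keep <- mass >= prune
    if (!all(keep)) {
      pruned_loss <- pruned_loss + sum(mass[!keep])
      lower <- lower[keep]
      upper <- upper[keep]
      mass <- mass[keep]
    }
    if (length(mass) > max_states) {
      stop(sprintf(
        "state space exceeded %g states at trial %d; raise `prune`",
        max_states, t))
    }
  }
  scored <- switch(score_policy,
                   drop_first = seq_len(n_trials) > 1L,
                   all = rep(TRUE, n_trials),
                   training = rep(FALSE, n_trials))
  expected <- if (any(scored)) 100 * mean(traj[scored]) else NA_real_
  list(trajectory = traj,
       expected_accuracy = expected,
       final_distribution = list(lower = lower, upper = upper, mass = mass),
       pruned_loss = pruned_loss)
}

#' Oracle-predicted block accuracies for a full condition run
#'
#' Chains the forward pass over block 1 and block 2 of a design (training
#' does not enter: block 1 starts from the initial window unless the
#' design carries training over, which would require propagating training
#' too — done here when requested).
#'
#' @param params A [participant_params()].
#' @param condition A [condition_spec()] or label.
#' @param design An [experiment_design()].
#' @return List with `block1` and `block2` forward results (see
#'   [forward_accuracy_trajectory()]).
#' @export
predict_block_accuracy <- function(params, condition,
                                   design = experiment_design()) {
  if (is.character(condition)) condition <- condition_spec(condition)
  stopifnot(inherits(condition, "condition"),
            inherits(design, "experiment_design"))
  offset <- 0L
  start_dist <- NULL
  if (design$carry_training_into_block1 && design$training_trials > 0L) {
    tr <- forward_accuracy_trajectory(params, design$training_rule,
                                      design$training_trials,
                                      start_window = design$initial_window,
                                      score_policy = "training",
                                      trial_offset = offset)
    start_dist <- tr$final_distribution
  }
  offset <- design$training_trials
  b1 <- forward_accuracy_trajectory(params, condition$block1_rule,
                                    design$block_trials,
                                    start_window = design$initial_window,
                                    start_distribution = start_dist,
                                    trial_offset = offset)
  offset <- offset + design$block_trials
  b2_dist <- if (design$carry_block1_into_block2) b1$final_distribution
             else NULL
  b2 <- forward_accuracy_trajectory(params, condition$block2_rule,
                                    design$block_trials,
                                    start_window = design$initial_window,
                                    start_distribution = b2_dist,
                                    trial_offset = offset)
  list(block1 = b1, block2 = b2)
}

#' Calibrate responder parameters to a target block-1 accuracy
#'
#' Finds responder parameters whose oracle-predicted block-1 scored
#' accuracy (hard rule, 80 trials from the initial window, first trial
#' unscored) matches `target_accuracy_pct`. The block-1 accuracy is
#' decreasing in the distance between `mean_ms` and the window midpoint
#' and decreasing in `sd_ms`, so the search is a grid over the non-free /
#' outer field combined with bisection over the free field:
#'
#' * `free = "mean_ms"`: bisect the mean on the branch below the window
#'   midpoint, at fixed `sd_ms`.
#' * `free = "sd_ms"`: bisect the spread at fixed `mean_ms`.
#' * `free = c("mean_ms", "sd_ms")`: bisect the mean for each spread on a
#'   grid over `sd_bounds`; among admissible solutions the one whose
#'   spread is closest to `sd_prior` is returned (default 100 ms, a
#'   scalar-timing Weber fraction of ~0.1 at the 1-s target).
#'
#' Fails with an explicit error stating the attainable accuracy range when
#' the target cannot be reached within the bounds.
#'
#' @param target_accuracy_pct Target block-1 scored accuracy in percent,
#'   in `(0, 100)`.
#' @param free Character vector of free fields (`"mean_ms"`, `"sd_ms"`).
#' @param mean_ms,sd_ms Values used when the respective field is fixed.
#' @param mean_bounds,sd_bounds Search bounds for the free fields.
#' @param lapse_rate,lapse_spread_ms Fixed lapse model (defaults 0.02 and
#'   1000 ms).
#' @param sd_prior Preferred spread when both fields are free.
#' @param sd_grid_n Grid resolution over `sd_bounds` when both are free.
#' @param rule,n_trials,start_window The block-1 protocol being matched.
#' @param tol_pp Required agreement between achieved and target accuracy
#'   (percentage points, default 0.5).
#' @return A [participant_params()] with attributes
#'   `achieved_accuracy_pct` (oracle prediction) and `target_accuracy_pct`.
#' @export
calibrate_params <- function(target_accuracy_pct,
                             free = c("mean_ms", "sd_ms"),
                             mean_ms = 1000, sd_ms = 100,
                             mean_bounds = c(700, 1045),
                             sd_bounds = c(50, 200),
                             lapse_rate = 0.02, lapse_spread_ms = 1000,
                             sd_prior = 100, sd_grid_n = 7,
                             rule = rule_hard(), n_trials = 80,
                             start_window = tolerance_window(990, 1100),
                             tol_pp = 0.5) {
  if (!is.finite(target_accuracy_pct) ||
      target_accuracy_pct <= 0 || target_accuracy_pct >= 100) {
    stop("target_accuracy_pct must lie in (0, 100)")
  }
  free <- match.arg(free, c("mean_ms", "sd_ms"), several.ok = TRUE)
  predict1 <- function(m, s) {
    p <- participant_params(mean_ms = m, sd_ms = s, lapse_rate = lapse_rate,
                            lapse_spread_ms = lapse_spread_ms)
    forward_accuracy_trajectory(p, rule, n_trials,
                                start_window = start_window)$expected_accuracy
  }
  # bisection of a monotone-decreasing f over [lo, hi] towards `target`
  bisect <- function(f, lo, hi, target, iter = 60) {
    flo <- f(lo)
    fhi <- f(hi)
    if ((flo - target) * (fhi - target) > 0) return(NULL)
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target) < tol_pp / 10 || (hi - lo) < 1e-6) {
        return(list(x = mid, achieved = fm))
      }
      if ((flo - target) * (fm - target) <= 0) {
        hi <- mid
        fhi <- fm
      } else {
        lo <- mid
        flo <- fm
      }
    }
    list(x = mid, achieved = fm)
  }
  mid_w <- (start_window$lower_ms + start_window$upper_ms) / 2

  solutions <- list()
  if (identical(sort(free), sort(c("mean_ms", "sd_ms")))) {
    sd_grid <- seq(sd_bounds[1], sd_bounds[2], length.out = sd_grid_n)
    for (s in sd_grid) {
      sol <- bisect(function(m) predict1(m, s),
                    lo = mean_bounds[1], hi = min(mean_bounds[2], mid_w),
                    target = target_accuracy_pct)
      if (!is.null(sol) &&
          abs(sol$achieved - target_accuracy_pct) <= tol_pp) {
        solutions[[length(solutions) + 1]] <-
          list(mean = sol$x, sd = s, achieved = sol$achieved)
      }
    }
    if (length(solutions)) {
      pick <- which.min(vapply(solutions,
                               function(z) abs(z$sd - sd_prior), 0))
      best <- solutions[[pick]]
    } else best <- NULL
  } else if (identical(free, "mean_ms")) {
    sol <- bisect(function(m) predict1(m, sd_ms),
                  lo = mean_bounds[1], hi = min(mean_bounds[2], mid_w),
                  target = target_accuracy_pct)
    best <- if (!is.null(sol) &&
                abs(sol$achieved - target_accuracy_pct) <= tol_pp) {
      list(mean = sol$x, sd = sd_ms, achieved = sol$achieved)
    }
  } else {
    sol <- bisect(function(s) predict1(mean_ms, s),
                  lo = sd_bounds[1], hi = sd_bounds[2],
                  target = target_accuracy_pct)
    best <- if (!is.null(sol) &&
                abs(sol$achieved - target_accuracy_pct) <= tol_pp) {
      list(mean = mean_ms, sd = sol$x, achieved = sol$achieved)
    }
  }

  if (is.null(best)) {
    # report attainable range at the search corners
    corners <- c(
      predict1(if ("mean_ms" %in% free) mid_w else mean_ms,
               if ("sd_ms" %in% free) sd_bounds[1] else sd_ms),
      predict1(if ("mean_ms" %in% free) mean_bounds[1] else mean_ms,
               if ("sd_ms" %in% free) sd_bounds[2] else sd_ms))
    stop(sprintf(
      paste0("target accuracy %.2f%% is unattainable within the bounds; ",
             "attainable range is roughly [%.2f%%, %.2f%%]"),
      target_accuracy_pct, min(corners), max(corners)))
  }
  out <- participant_params(mean_ms = best$mean, sd_ms = best$sd,
                            lapse_rate = lapse_rate,
                            lapse_spread_ms = lapse_spread_ms)
  attr(out, "achieved_accuracy_pct") <- best$achieved
  attr(out, "target_accuracy_pct") <- target_accuracy_pct
  out
}
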