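#' Group accuracy summary (condition x block)
#'
#' Per condition and experimental block: mean accuracy, sample standard
#' deviation (n - 1 denominator) and group size. Accepts either a list of
#' `participant_record`s or a per-participant summary data frame with
#' columns `condition`, `accuracy_block1`, `accuracy_block2`. Excluded
#' participants (`excluded == TRUE`) are omitted.
#'
#' @param x Records or per-participant summary data frame.
#' @return Data frame with columns `condition`, `block` (`"block1"`,
#'   `"block2"`), `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- participant_summary(x)
  stopifnot(is.data.frame(x),
            all(c("condition", "accuracy_block1", "accuracy_block2") %in%
                  names(x)))
  if ("excluded" %in% names(x)) x <- x[!x$excluded, , drop = FALSE]
  if (!nrow(x)) stop("no retained participants to summarize")
  out <- do.call(rbind, lapply(split(x, x$condition), function(g) {
    data.frame(condition = g$condition[1],
               block = c("block1", "block2"),
               mean = c(mean(g$accuracy_block1), mean(g$accuracy_block2)),
               sd = c(stats::sd(g$accuracy_block1),
                      stats::sd(g$accuracy_block2)),
               n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published group accuracy summary of the paradigm's validation study
#'
#' The group means, standard deviations and sizes of scored staircase
#' accuracy in the two experimental blocks for the four feedback
#' conditions, as reported in the paradigm's validation study with healthy
#' adults (N = 113). Used as the worked-example input for the contrast
#' machinery and as the calibration target for replication simulations.
#'
#' @return A group summary data frame as produced by [summarize_cohort()].
#' @export
reference_accuracy_summary <- function() {
  data.frame(
    condition = rep(c("confirmation", "violation", "violation_inhibiting",
                      "violation_enhancing"), each = 2),
    block = rep(c("block1", "block2"), 4),
    mean = c(15.73, 16.46, 17.18, 53.66, 17.24, 50.46, 15.96, 49.55),
    sd = c(7.16, 7.81, 5.53, 9.70, 6.43, 9.01, 5.96, 12.49),
    n = rep(c(28L, 28L, 29L, 28L), each = 2),
    stringsAsFactors = FALSE
  )
}

#' Pooled block-1 mean accuracy of the published summary
#'
#' The n-weighted mean of the four block-1 group means; the default
#' calibration target for replication simulations.
#'
#' @return A percentage.
#' @export
reference_block1_target <- function() {
  s <- reference_accuracy_summary()
  b1 <- s[s$block == "block1", ]
  sum(b1$mean * b1$n) / sum(b1$n)
}

.get_cell <- function(summary, group, block) {
  row <- summary[summary$condition == group & summary$block == block, ]
  if (nrow(row) != 1L) {
    stop(sprintf("group '%s' / %s not found in summary", group, block))
  }
  row
}

.pooled_contrast <- function(m_a, m_b, v_pooled, df, n_a, n_b, family,
                             conf_level) {
  diff <- m_a - m_b
  se <- sqrt(v_pooled * (1 / n_a + 1 / n_b))
  tstat <- diff / se
  p_adj <- min(1, family * 2 * stats::pt(-abs(tstat), df))
  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - alpha / (2 * family), df)
  list(m_diff = diff, ci_low = diff - tcrit * se,
       ci_high = diff + tcrit * se, p_adjusted = p_adj,
       se = se, df = df)
}

#' Post hoc mean difference between two groups in one block
#'
#' `M_diff = M_a - M_b` for the given block, straight from the group
#' summary. When the per-participant data are supplied, a Bonferroni-
#' adjusted pooled-variance t comparison is added: the error variance is
#' pooled over all groups in the data (the one-way ANOVA mean square,
#' df = N - G), and both the adjusted p value and the simultaneous
#' confidence interval use the family size (default: all pairwise
#' comparisons among the groups present).
#'
#' @param summary A group summary from [summarize_cohort()].
#' @param group_a,group_b Condition labels.
#' @param block `"block1"` or `"block2"`.
#' @param data Optional per-participant data frame (`condition`,
#'   `accuracy_block1`, `accuracy_block2`).
#' @param family Bonferroni family size; default `choose(G, 2)`.
#' @param conf_level Confidence level before adjustment (default 0.95).
#' @return A one-row data frame: `group_a`, `group_b`, `scope`, `m_diff`,
#'   `ci_low`, `ci_high`, `p_adjusted`, `method`.
#' @export
posthoc_mean_difference <- function(summary, group_a, group_b,
                                    block = "block2", data = NULL,
                                    family = NULL, conf_level = 0.95) {
  block <- match.arg(block, c("block1", "block2"))
  a <- .get_cell(summary, group_a, block)
  b <- .get_cell(summary, group_b, block)
  res <- data.frame(group_a = group_a, group_b = group_b,
                    scope = block, m_diff = a$mean - b$mean,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_adjusted = NA_real_, method = "none",
                    stringsAsFactors = FALSE)
  if (!is.null(data)) {
    col <- paste0("accuracy_", block)
    groups <- split(data[[col]], data$condition)
    G <- length(groups)
    if (is.null(family)) family <- choose(G, 2)
    ns <- lengths(groups)
    v_pooled <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
      (sum(ns) - G)
    pc <- .pooled_contrast(mean(groups[[group_a]]), mean(groups[[group_b]]),
                           v_pooled, sum(ns) - G,
                           ns[[group_a]], ns[[group_b]], family, conf_level)
    res$m_diff <- pc$m_diff
    res$ci_low <- pc$ci_low
    res$ci_high <- pc$ci_high
    res$p_adjusted <- pc$p_adjusted
    res$method <- "bonferroni"
  }
  res
}

#' Marginal (repeated-measures) mean difference between two groups
#'
#' Difference of the per-group accuracies averaged over the two
#' experimental blocks:
#' `mean(M_a_b1, M_a_b2) - mean(M_b_b1, M_b_b2)`. With per-participant
#' data, the comparison is run on subject means across blocks with the
#' same pooled-variance Bonferroni machinery as
#' [posthoc_mean_difference()].
#'
#' @inheritParams posthoc_mean_difference
#' @return A one-row data frame as in [posthoc_mean_difference()], with
#'   `scope = "marginal"`.
#' @export
marginal_mean_difference <- function(summary, group_a, group_b, data = NULL,
                                     family = NULL, conf_level = 0.95) {
  ma <- mean(c(.get_cell(summary, group_a, "block1")$mean,
               .get_cell(summary, group_a, "block2")$mean))
  mb <- mean(c(.get_cell(summary, group_b, "block1")$mean,
               .get_cell(summary, group_b, "block2")$mean))
  res <- data.frame(group_a = group_a, group_b = group_b,
                    scope = "marginal", m_diff = ma - mb,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_adjusted = NA_real_, method = "none",
                    stringsAsFactors = FALSE)
  if (!is.null(data)) {
    subj_mean <- (data$accuracy_block1 + data$accuracy_block2) / 2
    groups <- split(subj_mean, data$condition)
    G <- length(groups)
    if (is.null(family)) family <- choose(G, 2)
    ns <- lengths(groups)
    v_pooled <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
      (sum(ns) - G)
    pc <- .pooled_contrast(mean(groups[[group_a]]), mean(groups[[group_b]]),
                           v_pooled, sum(ns) - G,
                           ns[[group_a]], ns[[group_b]], family, conf_level)
    res$m_diff <- pc$m_diff
    res$ci_low <- pc$ci_low
    res$ci_high <- pc$ci_high
    res$p_adjusted <- pc$p_adjusted
    res$method <- "bonferroni"
  }
  res
}

.safe_f <- function(ss_effect, df1, ss_error, df2) {
  if (ss_effect <= 0) {
    return(list(F = 0, p = 1, eta = 0))
  }
  if (ss_error <= 0) {
    return(list(F = Inf, p = 0, eta = 1))
  }
  F <- (ss_effect / df1) / (ss_error / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       eta = ss_effect / (ss_effect + ss_error))
}

#' Mixed-design (split-plot) ANOVA for a groups x 2-blocks layout
#'
#' The classical univariate decomposition for one between-subject factor
#' (condition) crossed with a two-level within-subject factor (block).
#' With two within levels the decomposition is exact through subject means
#' `m_i = (y_i1 + y_i2) / 2` and difference scores `d_i = y_i2 - y_i1`:
#' the between part is a one-way ANOVA on `m_i`, the within part a one-way
#' ANOVA on `d_i` whose intercept tests the time main effect. For
#' unbalanced groups the time effect tests the unweighted mean of the
#' group difference-score means (Type III convention). Partial eta squared
#' is `SS_effect / (SS_effect + SS_error)` for every effect.
#'
#' Planned contrasts are evaluated on the difference scores: the contrast
#' estimate is `sum(w_g * dbar_g)` with the within-error mean square, so
#' each contrast is an F test with 1 and N - G degrees of freedom.
#'
#' @param data Per-participant data frame with `condition`,
#'   `accuracy_block1`, `accuracy_block2` (any pre/post pair works).
#' @param contrasts Named list of contrast weight vectors over the sorted
#'   condition levels; `NULL` (default) uses the paradigm's three planned
#'   contrasts when the four standard conditions are present, none
#'   otherwise.
#' @return A list with `anova` (data frame: `effect`, `ss`, `df1`,
#'   `ss_error`, `df2`, `F`, `p`, `eta_sq_p`) and `contrasts` (data frame:
#'   `contrast`, `estimate`, `F`, `df1`, `df2`, `p`, `eta_sq_p`).
#' @export
mixed_anova <- function(data, contrasts = NULL) {
  stopifnot(is.data.frame(data),
            all(c("condition", "accuracy_block1", "accuracy_block2") %in%
                  names(data)))
  cond <- factor(data$condition)
  levels_ <- levels(cond)
  G <- nlevels(cond)
  ns <- as.vector(table(cond))
  if (any(ns < 2L)) stop("every group needs at least 2 participants")
  N <- nrow(data)
  m <- (data$accuracy_block1 + data$accuracy_block2) / 2
  d <- data$accuracy_block2 - data$accuracy_block1

  m_bar <- tapply(m, cond, mean)
  d_bar <- tapply(d, cond, mean)
  grand_m <- mean(m)
  grand_d_w <- mean(d)

  # between-subject part (classical metric: x2 relative to the m ANOVA)
  ss_cond <- 2 * sum(ns * (m_bar - grand_m)^2)
  ss_serr <- 2 * sum((m - m_bar[as.integer(cond)])^2)
  # within-subject part (classical metric: d-based SS / 2)
  mu_u <- mean(d_bar)  # unweighted marginal time effect (Type III)
  ss_time <- 0.5 * mu_u^2 * G^2 / sum(1 / ns)
  ss_int <- 0.5 * sum(ns * (d_bar - grand_d_w)^2)
  ss_werr <- 0.5 * sum((d - d_bar[as.integer(cond)])^2)

  eff_cond <- .safe_f(ss_cond, G - 1, ss_serr, N - G)
  eff_time <- .safe_f(ss_time, 1, ss_werr, N - G)
  eff_int <- .safe_f(ss_int, G - 1, ss_werr, N - G)
  anova_tab <- data.frame(
    effect = c("condition", "time", "time:condition"),
    ss = c(ss_cond, ss_time, ss_int),
    df1 = c(G - 1L, 1L, G - 1L),
    ss_error = c(ss_serr, ss_werr, ss_werr),
    df2 = rep(N - G, 3L),
    F = c(eff_cond$F, eff_time$F, eff_int$F),
    p = c(eff_cond$p, eff_time$p, eff_int$p),
    eta_sq_p = c(eff_cond$eta, eff_time$eta, eff_int$eta),
    stringsAsFactors = FALSE
  )

  if (is.null(contrasts)) {
    std <- c("confirmation", "violation", "violation_inhibiting",
             "violation_enhancing")
    if (setequal(levels_, std)) {
      w <- function(x) stats::setNames(x, std)[levels_]
      contrasts <- list(
        confirmation_vs_violation = w(c(1, -1, 0, 0)),
        inhibiting_vs_enhancing = w(c(0, 0, 1, -1)),
        experiment1_vs_experiment2 = w(c(0.5, 0.5, -0.5, -0.5))
      )
    } else contrasts <- list()
  }
  contrast_tab <- NULL
  if (length(contrasts)) {
    ms_werr <- ss_werr / (N - G)
    rows <- lapply(names(contrasts), function(nm) {
      wgt <- contrasts[[nm]]
      if (length(wgt) != G) stop("contrast length must equal group count")
      est <- sum(wgt * d_bar)
      ss_c <- 0.5 * est^2 / sum(wgt^2 / ns)
      eff <- .safe_f(ss_c, 1, ss_werr, N - G)
      data.frame(contrast = nm, estimate = est, F = eff$F, df1 = 1L,
                 df2 = N - G, p = eff$p, eta_sq_p = eff$eta,
                 stringsAsFactors = FALSE)
    })
    contrast_tab <- do.call(rbind, rows)
  }
  list(anova = anova_tab, contrasts = contrast_tab)
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)`, order-preserving.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]`.
#' @param family_size Number of comparisons in the family (default:
#'   `length(p_values)`).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  pmin(1, p_values * family_size)
}

#' Summary of the manipulation-check self-assessment items
#'
#' Per-condition mean (SD) of the three self-assessment columns:
#' post-assessment of block 1, prediction for block 2, post-assessment of
#' block 2. These are pass-through data (never simulated by this package).
#'
#' @param data Data frame with `condition` and the item columns.
#' @param items Character vector of the item column names.
#' @return Long data frame: `condition`, `item`, `mean`, `sd`, `n`; `sd`
#'   is `NA` (with a warning) for single-row cells.
#' @export
manipulation_check_summary <- function(data,
                                       items = c("post_block1",
                                                 "prediction_block2",
                                                 "post_block2")) {
  stopifnot(is.data.frame(data), "condition" %in% names(data))
  missing <- setdiff(items, names(data))
  if (length(missing)) {
    stop("missing self-assessment columns: ", paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(data, data$condition), function(g) {
    do.call(rbind, lapply(items, function(it) {
      data.frame(condition = g$condition[1], item = it,
                 mean = mean(g[[it]]), sd = stats::sd(g[[it]]),
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  if (anyNA(out$sd)) {
    warning("SD undefined for single-participant cells")
  }
  out
}
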