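# shared test utilities

# brute-force split-plot sums of squares for a balanced groups x 2-times
# layout, computed straight from subject means and difference scores;
# kept independent of mixed_anova()'s internals
split_plot_ss <- function(condition, y1, y2) {
  cond <- factor(condition)
  ns <- as.vector(table(cond))
  stopifnot(length(unique(ns)) == 1L)  # balanced oracle
  m <- (y1 + y2) / 2
  d <- y2 - y1
  m_bar <- tapply(m, cond, mean)
  d_bar <- tapply(d, cond, mean)
  list(
    ss_condition = 2 * sum(ns * (m_bar - mean(m))^2),
    ss_subject_error = 2 * sum((m - m_bar[as.integer(cond)])^2),
    ss_time = 0.5 * sum(ns) * mean(d)^2,
    ss_interaction = 0.5 * sum(ns * (d_bar - mean(d))^2),
    ss_within_error = 0.5 * sum((d - d_bar[as.integer(cond)])^2)
  )
}

# quick per-participant accuracy table for stats tests
make_accuracy_table <- function(condition, block1, block2) {
  data.frame(participant_id = sprintf("P%03d", seq_along(condition)),
             condition = condition,
             accuracy_block1 = block1,
             accuracy_block2 = block2,
             stringsAsFactors = FALSE)
}
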