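# Independent oracles and fixture builders used across the suite.

# Random balanced duplicate cell: p labs, 2 replicates each, classical
# lab-bias + replicate-error model.
random_duplicate_cell <- function(p = 14, mu = -25, s_r = 0.1, s_L = 0.3) {
  vals <- lapply(seq_len(p), function(i) mu + rnorm(1, 0, s_L) + rnorm(2, 0, s_r))
  as_ilc_cell(vals)
}

# Brute-force one-way variance-component oracle via stats::aov mean squares
# (balanced cells only): an independent route to s_r and s_R.
aov_components_oracle <- function(cell) {
  stopifnot(length(unique(cell$n_i)) == 1)
  n <- cell$n_i[1]
  df <- data.frame(
    y = unlist(cell$values, use.names = FALSE),
    lab = factor(rep(cell$labs, each = n)))
  ms <- summary(stats::aov(y ~ lab, data = df))[[1]][["Mean Sq"]]
  s_r2 <- ms[2]
  s_L2 <- max((ms[1] - ms[2]) / n, 0)
  list(mean = mean(df$y), s_r = sqrt(s_r2), s_R = sqrt(s_r2 + s_L2),
       degenerate = (ms[1] - ms[2]) <= 0)
}

# Two-pass textbook computation, written independently of the package path:
# explicit loops, no pooled shortcuts.
two_pass_components_oracle <- function(cell) {
  ybar <- sapply(cell$values, mean)
  N <- sum(cell$n_i)
  grand <- sum(unlist(cell$values)) / N
  ssw <- 0
  for (v in cell$values) for (y in v) ssw <- ssw + (y - mean(v))^2
  s_r2 <- ssw / (N - length(cell$values))
  p <- length(cell$values)
  ssb <- sum(cell$n_i * (ybar - sum(cell$n_i * ybar) / N)^2)
  msb <- ssb / (p - 1)
  nbar <- (N - sum(cell$n_i^2) / N) / (p - 1)
  s_L2 <- max((msb - s_r2) / nbar, 0)
  list(s_r = sqrt(s_r2), s_R = sqrt(s_r2 + s_L2))
}

# Minimal long CSV writer for I/O tests.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
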