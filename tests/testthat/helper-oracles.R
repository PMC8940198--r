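# Independent brute-force oracles used to cross-check the package's
# statistics on small inputs.  These deliberately re-derive everything
# from first principles (explicit loops, textbook formulas) rather than
# calling the implementation under test.

# Plug-in entropy rate of a collapsed state sequence, tallied by loops.
oracle_entropy <- function(states) {
  keep <- c(TRUE, states[-1] != states[-length(states)])
  states <- states[keep]
  from <- states[-length(states)]
  to <- states[-1]
  n <- length(from)
  H <- 0
  for (s in unique(from)) {
    sel <- from == s
    pi_s <- sum(sel) / n
    dest <- to[sel]
    for (d in unique(dest)) {
      p <- sum(dest == d) / sum(sel)
      H <- H - pi_s * p * log2(p)
    }
  }
  H
}

# All sequences of given length over states 0..(k-1) with no two equal
# consecutive entries.
all_nodup_sequences <- function(k, len) {
  seqs <- as.list(0:(k - 1))
  for (pos in seq_len(len - 1)) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(0:(k - 1), s[length(s)]), function(nx) c(s, nx))
    }), recursive = FALSE)
  }
  seqs
}

# Textbook one-way ANOVA from explicit sums of squares.
oracle_anova_F <- function(values, group) {
  group <- factor(group)
  grand <- mean(values)
  ss_between <- sum(tapply(values, group, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(values, group, function(v) (v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  (ss_between / df1) / (ss_within / df2)
}

# Pooled-variance two-sample t from the textbook formula.
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Least-squares coefficients from the normal equations.
oracle_ls_coef <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Write a session-log data frame to a temp file and return the path.
write_log_fixture <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Slow reference path simulator for the cycle-uniform mixture family,
# re-derived step by step so generator tests do not reuse the package's
# vectorised path construction.
simulate_mixture_path_test <- function(lambda, n) {
  s <- integer(n + 1)
  s[1] <- sample(0:7, 1)
  for (t in 1:n) {
    s[t + 1] <- if (runif(1) < lambda)
      sample(setdiff(0:7, s[t]), 1) else (s[t] + 1) %% 8
  }
  s
}
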