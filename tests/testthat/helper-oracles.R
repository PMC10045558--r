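# Independent oracles used by the tests; deliberately written from first
# principles, not via the package's own code paths.

# two-group log-rank chi-square with hypergeometric variance
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exhaustive permutation p-value for the log-rank statistic
oracle_perm_logrank_p <- function(time, event, group) {
  n <- length(time)
  g <- factor(group)
  n1 <- sum(g == levels(g)[1L])
  obs <- oracle_logrank_chisq(time, event, g)
  idx <- utils::combn(n, n1)
  stats <- apply(idx, 2L, function(i) {
    gg <- factor(ifelse(seq_len(n) %in% i, "a", "b"))
    oracle_logrank_chisq(time, event, gg)
  })
  mean(stats >= obs - 1e-12)
}

# product-limit estimator for uncensored data: 1 - ECDF at event times
oracle_km_uncensored <- function(times, t) {
  mean(times > t)
}

# pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}
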