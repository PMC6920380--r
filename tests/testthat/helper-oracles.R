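# Brute-force reference implementations, kept independent of the package
# code paths they check.

# Paired t from the explicit difference formula.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = tstat, df = n - 1,
       p_value = 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE))
}

# One-way ANOVA from the explicit sum-of-squares decomposition.
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(statistic = F, df = c(df1, df2),
       p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Step-down Sidak adjustment written as an explicit per-index maximum.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(seq_len(k), function(j) {
      1 - (1 - p[ord[j]])^(m - j + 1)
    }, numeric(1))
    adj[ord[k]] <- max(vals)
  }
  adj
}

# Grubbs decision with the critical value found by numerically inverting
# the Bonferroni tail probability, instead of the closed-form quantile.
oracle_grubbs_decision <- function(x, alpha) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / stats::sd(x)
  p_of_g <- function(g) {
    denom <- (n - 1)^2 - n * g^2
    if (denom <= 0) return(0)
    ts <- sqrt((n - 2) * n * g^2 / denom)
    min(1, 2 * n * stats::pt(ts, n - 2, lower.tail = FALSE))
  }
  g_max <- (n - 1) / sqrt(n)
  crit <- stats::uniroot(function(g) p_of_g(g) - alpha,
                         lower = 1e-6, upper = g_max - 1e-9,
                         tol = 1e-12)$root
  list(G = G, critical = crit, outlier = G > crit)
}

# Two-pass mean/SD threshold, the brute-force counterpart of
# pooled_threshold().
oracle_threshold <- function(pixels) {
  m <- sum(pixels) / length(pixels)
  s <- sqrt(sum((pixels - m)^2) / (length(pixels) - 1))
  m - 0.5 * s
}
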