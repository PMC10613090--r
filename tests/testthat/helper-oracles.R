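# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# OLS by explicitly solving the normal equations.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Nearest-rank percentile by counting: smallest value with at least
# p% of observations <= it.
oracle_percentile <- function(values, p) {
  srt <- sort(values)
  n <- length(srt)
  if (p <= 0) return(srt[1])
  for (v in srt) {
    if (sum(srt <= v) >= p / 100 * n) return(v)
  }
  srt[n]
}

# Trim by exhaustive comparison against the enumerated thresholds.
oracle_trim_keep <- function(values, lower_pct, upper_pct) {
  lo <- oracle_percentile(values, lower_pct)
  hi <- oracle_percentile(values, upper_pct)
  !is.na(values) & values > lo & values < hi
}

# Saturated 2x2 logistic MLE: log OR = cross-product ratio, Woolf SE.
oracle_2x2 <- function(a, b, c, d) {
  list(log_or = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Expand a 2x2 table into outcome/exposure vectors.
expand_2x2 <- function(a, b, c, d) {
  list(
    outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    exposure = c(rep(1, a + b), rep(0, c + d))
  )
}
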