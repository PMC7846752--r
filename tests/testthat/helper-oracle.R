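# Brute-force statistical oracle: sorted order statistics and direct
# formulas, written independently of the package implementation.

oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_descriptive <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(
    n = n,
    min = sort(x)[1],
    max = sort(x)[n],
    mean = m,
    sd = if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_,
    median = oracle_quantile7(x, 0.5),
    q1 = oracle_quantile7(x, 0.25),
    q3 = oracle_quantile7(x, 0.75),
    range = sort(x)[n] - sort(x)[1]
  )
}

oracle_spread <- function(x) {
  med <- oracle_quantile7(x, 0.5)
  absdev <- abs(x - med)
  mad_raw <- oracle_quantile7(absdev, 0.5)
  list(
    mad_raw = mad_raw,
    mad_norm = 1.4826 * mad_raw,
    mad_q3 = oracle_quantile7(absdev, 0.75),
    iqr = oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
  )
}

# windows recomputed from first principles for cross-checks
oracle_windows <- function(x, mad_variant = "q3") {
  d <- oracle_descriptive(x)
  s <- oracle_spread(x)
  mad <- if (mad_variant == "q3") s$mad_q3 else s$mad_norm
  list(
    two_sd = c(d$mean - 2 * d$sd, d$mean + 2 * d$sd),
    three_mad = c(d$median - 3 * mad, d$median + 3 * mad),
    tukey_iqr = c(d$q1 - 1.5 * s$iqr, d$q3 + 1.5 * s$iqr),
    two_permil = c(d$mean - 2, d$mean + 2)
  )
}
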