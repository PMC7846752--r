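# Per-community descriptive and robust statistics, normality testing,
# and poolability of neighbouring communities.

.check_values <- function(values, min_n = 1) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (length(values) < min_n) {
    stop("need at least ", min_n, " values, got ", length(values),
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values contain non-finite entries",
                                    call. = FALSE)
  invisible(values)
}

#' Descriptive statistics for one community
#'
#' Computes n, min, max, mean, sample standard deviation (n-1 denominator;
#' `NA` for a single observation), median, the first and third quartiles,
#' and the total range. Quartiles use linear interpolation of order
#' statistics, by default R's type 7 rule (`h = (n-1)p + 1`); type 2 is
#' offered for users who prefer the averaging convention.
#'
#' @param values Numeric vector of delta values, permil (any single scale).
#' @param quantile_type Quantile algorithm, 7 (default) or 2.
#' @return A one-row tibble with columns `n`, `min`, `max`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `range`.
#' @export
#' @examples
#' descriptive_stats(c(1, 2, 3, 4)) # q1 = 1.75, q3 = 3.25
descriptive_stats <- function(values, quantile_type = 7) {
  .check_values(values, 1)
  if (!quantile_type %in% c(2, 7)) {
    stop("quantile_type must be 2 or 7", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  tibble::tibble(
    n = length(values),
    min = min(values),
    max = max(values),
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else NA_real_,
    median = stats::median(values),
    q1 = q[1],
    q3 = q[2],
    range = max(values) - min(values)
  )
}

#' Robust spread measures for one community
#'
#' The "modifying values" used to build locality windows: the raw median
#' absolute deviation from the median (`mad_raw`), its normal-consistent
#' scaling `mad_norm = 1.4826 * mad_raw`, the skew-tolerant `mad_q3`
#' (75th percentile of the absolute deviations from the median, same
#' quantile rule as [descriptive_stats()]), and the interquartile range.
#'
#' @inheritParams descriptive_stats
#' @return A one-row tibble with columns `mad_raw`, `mad_norm`, `mad_q3`,
#'   `iqr`.
#' @export
#' @examples
#' robust_spread(c(1, 1, 2, 2, 4, 6, 9)) # mad_raw 1, mad_norm 1.4826
robust_spread <- function(values, quantile_type = 7) {
  .check_values(values, 2)
  absdev <- abs(values - stats::median(values))
  mad_raw <- stats::median(absdev)
  q <- stats::quantile(values, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  tibble::tibble(
    mad_raw = mad_raw,
    mad_norm = 1.4826 * mad_raw,
    mad_q3 = stats::quantile(absdev, 0.75, type = quantile_type,
                             names = FALSE),
    iqr = q[2] - q[1]
  )
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the pieces the
#' locality screen needs. Normality at `alpha = 0.05` decides which MAD
#' variant a community's screen uses (see [select_mad_variant()]).
#'
#' @inheritParams descriptive_stats
#' @return A one-row tibble with columns `W`, `p`, `n`.
#' @export
shapiro_wilk <- function(values) {
  .check_values(values, 3)
  if (length(values) > 5000) stop("n > 5000 not supported", call. = FALSE)
  if (max(values) == min(values)) {
    stop("Shapiro-Wilk test undefined for constant input", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value,
                 n = length(values))
}

#' Test whether neighbouring communities can be pooled
#'
#' Two groups are compared with a two-sided Student's t test (pooled
#' variance by default, Welch by flag); three or more with a
#' Kruskal-Wallis rank test. Communities are considered poolable when the
#' test fails to find a difference at level `alpha`.
#'
#' @param groups Named list of numeric vectors, one per community.
#' @param alpha Significance level (default 0.05).
#' @param var_equal For two groups: `TRUE` (default) for the classical
#'   pooled-variance t test, `FALSE` for Welch.
#' @return A one-row tibble with columns `test` (`"t_test"` or
#'   `"kruskal_wallis"`), `statistic`, `p`, `groups` (comma-joined names),
#'   `pooled`.
#' @export
poolability_tests <- function(groups, alpha = 0.05, var_equal = TRUE) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of at least two numeric vectors",
         call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns == 0)) {
    stop("empty group(s): ",
         paste(names(groups)[ns == 0], collapse = ", "), call. = FALSE)
  }
  lapply(groups, .check_values)
  labels <- names(groups) %||% as.character(seq_along(groups))
  if (length(groups) == 2) {
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    test <- "t_test"
  } else {
    ht <- stats::kruskal.test(groups)
    test <- "kruskal_wallis"
  }
  tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p = ht$p.value,
    groups = paste(labels, collapse = ","),
    pooled = ht$p.value > alpha
  )
}

#' Pool the samples of a tagged group of communities
#'
#' Merges the samples of every site carrying `pooling_group` into a single
#' analysis unit (e.g. the four Copper Age cemeteries around Rome), after
#' checking with [poolability_tests()] that their \eqn{\delta^{18}O}
#' distributions are statistically indistinguishable. Pooling against a
#' failed test requires `override = TRUE` and is recorded in the result.
#'
#' @param samples Sample tibble (canonical columns).
#' @param sites Site registry tibble.
#' @param pooling_group Tag to pool, e.g. `"rome_copper_age"`.
#' @param value_col Column tested for poolability (default the V-PDB
#'   oxygen values; the choice does not affect the rank test and only
#'   rescales the t test).
#' @param alpha Significance level for the poolability test.
#' @param override Pool even when the test rejects (logged in the result).
#' @return A list with elements `code` (the pooling tag), `members`,
#'   `samples` (merged tibble), `test` (the [poolability_tests()] row) and
#'   `overridden`.
#' @export
pool_sites <- function(samples, sites, pooling_group,
                       value_col = "d18O_ca_vpdb", alpha = 0.05,
                       override = FALSE) {
  members <- sites$code[!is.na(sites$pooling_group) &
                          sites$pooling_group == pooling_group]
  if (length(members) == 0) {
    stop("unknown pooling_group: ", pooling_group, call. = FALSE)
  }
  if (length(members) < 2) {
    stop("pooling_group '", pooling_group, "' has fewer than two sites",
         call. = FALSE)
  }
  sub <- samples[samples$site_code %in% members, , drop = FALSE]
  groups <- split(sub[[value_col]], sub$site_code)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    stop("pooling_group '", pooling_group,
         "' has samples from fewer than two sites", call. = FALSE)
  }
  test <- poolability_tests(groups, alpha = alpha)
  if (!test$pooled && !override) {
    stop("sites {", paste(names(groups), collapse = ", "),
         "} differ (", test$test, " p = ", signif(test$p, 3),
         " <= ", alpha, "); refuse to pool without override = TRUE",
         call. = FALSE)
  }
  list(code = pooling_group, members = sort(names(groups)), samples = sub,
       test = test, overridden = !test$pooled && override)
}

#' Per-site summary table across scales
#'
#' Convenience wrapper mapping [descriptive_stats()] over sites on the
#' measured V-PDB scale, the converted V-SMOW scale and the carbon values,
#' mirroring how community tables are conventionally reported.
#'
#' @param samples Sample tibble.
#' @param quantile_type Passed to [descriptive_stats()].
#' @return Tibble with one row per site and prefixed stat columns
#'   (`d18O_vpdb_*`, `d18O_vsmow_*`, `d13C_*`).
#' @export
site_stats_table <- function(samples, quantile_type = 7) {
  per_site <- function(code) {
    sub <- samples[samples$site_code == code, , drop = FALSE]
    o <- sub$d18O_ca_vpdb[!is.na(sub$d18O_ca_vpdb)]
    cvals <- sub$d13C_ca_vpdb[!is.na(sub$d13C_ca_vpdb)]
    stat_row <- function(v, prefix) {
      if (length(v) == 0) {
        s <- descriptive_stats(0)[0, ]  # empty, keeps columns
        s[1, ] <- NA
        s$n <- 0L
      } else {
        s <- descriptive_stats(v, quantile_type)
      }
      names(s) <- paste0(prefix, "_", names(s))
      s
    }
    dplyr::bind_cols(
      tibble::tibble(site_code = code),
      stat_row(o, "d18O_vpdb"),
      stat_row(vpdb_to_vsmow(o), "d18O_vsmow"),
      stat_row(cvals, "d13C")
    )
  }
  dplyr::bind_rows(lapply(unique(samples$site_code), per_site))
}
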