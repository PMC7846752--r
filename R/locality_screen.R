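# The locality screen: per-community "local range" windows under four
# criteria and consensus outlier classification.
#
# Criteria: (a) mean +/- 2 sd, (b) median +/- 3 MAD (normal-consistent MAD
# when the community passes a Shapiro-Wilk normality test, the Q3 variant
# otherwise), (c) Tukey fences at 1.5 IQR beyond the quartiles, and
# (d) a fixed mean +/- 2 permil band. A sample flagged by every applied
# criterion is the consensus candidate for a non-local ("newcomer").

.WINDOW_METHODS <- c("two_sd", "three_mad_norm", "three_mad_q3",
                     "tukey_iqr", "two_permil")

#' Minimum-sample-size gate for the outlier screen
#'
#' Communities below `min_n` individuals (default 9) still receive
#' descriptive statistics and plots but no outlier screen: the window
#' statistics are too unstable to separate locals from newcomers.
#'
#' @param n Number of individuals with \eqn{\delta^{18}O} values.
#' @param min_n Gate threshold (default 9).
#' @return `TRUE` if the community is large enough to screen.
#' @export
sample_size_gate <- function(n, min_n = 9) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  n >= min_n
}

#' Choose the MAD variant from a normality test
#'
#' The 3-MAD criterion uses the normal-consistent MAD when the community's
#' values are compatible with a normal distribution (`p > alpha`) and the
#' skew-tolerant Q3 variant otherwise (`p <= alpha`, boundary counted as
#' non-normal).
#'
#' @param normality One-row tibble from [shapiro_wilk()] (needs column
#'   `p`).
#' @param alpha Significance level (default 0.05).
#' @return `"three_mad_norm"` or `"three_mad_q3"`.
#' @export
select_mad_variant <- function(normality, alpha = 0.05) {
  p <- normality$p
  if (is.null(p) || !is.finite(p)) stop("invalid normality result",
                                        call. = FALSE)
  if (p > alpha) "three_mad_norm" else "three_mad_q3"
}

#' Build one locality window
#'
#' Constructs the interval of \eqn{\delta^{18}O} values considered
#' compatible with local origin under a single criterion:
#' \describe{
#'   \item{two_sd}{`mean +/- 2 sd` (width `4 sd`)}
#'   \item{three_mad_norm / three_mad_q3}{`median +/- 3 mad_variant`
#'     (width `6 mad`)}
#'   \item{tukey_iqr}{`[q1 - 1.5 iqr, q3 + 1.5 iqr]` (width `4 iqr`)}
#'   \item{two_permil}{`mean +/- 2.0` permil (fixed width 4.0)}
#' }
#'
#' @param stats One-row tibble from [descriptive_stats()].
#' @param spread One-row tibble from [robust_spread()] (may be `NULL` for
#'   the methods that do not need it).
#' @param method One of `"two_sd"`, `"three_mad_norm"`, `"three_mad_q3"`,
#'   `"tukey_iqr"`, `"two_permil"`.
#' @return A one-row tibble with columns `method`, `center`, `lower`,
#'   `upper`.
#' @export
locality_window <- function(stats, spread = NULL, method) {
  method <- match.arg(method, .WINDOW_METHODS)
  need_spread <- method %in% c("three_mad_norm", "three_mad_q3", "tukey_iqr")
  if (need_spread && is.null(spread)) {
    stop("method '", method, "' needs robust spread measures", call. = FALSE)
  }
  win <- switch(method,
    two_sd = {
      if (is.na(stats$sd)) stop("two_sd window needs sd (n >= 2)",
                                call. = FALSE)
      c(stats$mean, stats$mean - 2 * stats$sd, stats$mean + 2 * stats$sd)
    },
    three_mad_norm = c(stats$median,
                       stats$median - 3 * spread$mad_norm,
                       stats$median + 3 * spread$mad_norm),
    three_mad_q3 = c(stats$median,
                     stats$median - 3 * spread$mad_q3,
                     stats$median + 3 * spread$mad_q3),
    tukey_iqr = c((stats$q1 + stats$q3) / 2,
                  stats$q1 - 1.5 * spread$iqr,
                  stats$q3 + 1.5 * spread$iqr),
    two_permil = c(stats$mean, stats$mean - 2, stats$mean + 2)
  )
  tibble::tibble(method = method, center = win[1], lower = win[2],
                 upper = win[3])
}

#' Build the full set of locality windows for a community
#'
#' Computes descriptive statistics, robust spread and (when `mad_variant =
#' "auto"`) a Shapiro-Wilk normality test from the community's own values,
#' then assembles the requested windows. `"mad"` in `methods` expands to
#' the selected variant.
#'
#' @param values Numeric vector of \eqn{\delta^{18}O} values for the
#'   community (single scale; windows are scale-equivariant).
#' @param methods Criteria to apply; default the four-criterion screen.
#' @param mad_variant `"auto"` (choose by normality at `alpha`), `"norm"`
#'   or `"q3"`.
#' @param alpha Significance level for the normality test.
#' @param quantile_type Passed to the underlying statistics.
#' @return Tibble of windows (one row per method) with the normality
#'   result attached as attribute `"normality"` when computed.
#' @export
locality_windows <- function(values,
                             methods = c("two_sd", "mad", "tukey_iqr",
                                         "two_permil"),
                             mad_variant = c("auto", "norm", "q3"),
                             alpha = 0.05, quantile_type = 7) {
  mad_variant <- match.arg(mad_variant)
  stats <- descriptive_stats(values, quantile_type)
  spread <- robust_spread(values, quantile_type)
  normality <- NULL
  if ("mad" %in% methods) {
    selected <- switch(mad_variant,
      norm = "three_mad_norm",
      q3 = "three_mad_q3",
      auto = {
        normality <- shapiro_wilk(values)
        select_mad_variant(normality, alpha)
      })
    methods[methods == "mad"] <- selected
  }
  methods <- match.arg(methods, .WINDOW_METHODS, several.ok = TRUE)
  out <- dplyr::bind_rows(lapply(methods, function(m) {
    locality_window(stats, spread, m)
  }))
  attr(out, "normality") <- normality
  out
}

#' Classify samples against locality windows
#'
#' A sample is flagged by a criterion iff its value lies strictly outside
#' that window (windows are closed; a value exactly on a bound is local).
#' Values within `boundary_tol` (default 0.05 permil, half a reporting
#' unit) of a bound are annotated as boundary cases so they can be
#' discussed rather than silently classified. Windows are computed from
#' the full community sample including the candidates themselves (single
#' pass, no leave-one-out).
#'
#' @param samples Tibble (or data frame) with columns `sample_id` and
#'   `value`, on the same scale as the windows.
#' @param windows Tibble of windows from [locality_windows()].
#' @param boundary_tol Half-width of the boundary annotation band, permil.
#' @return Tibble with one row per sample: `sample_id`, `value`, one
#'   logical `out_<method>` column per window, `consensus_count`,
#'   `is_consensus_outlier` (flagged by every applied criterion) and
#'   `boundary`.
#' @export
classify_outliers <- function(samples, windows, boundary_tol = 0.05) {
  if (nrow(windows) < 1) stop("need at least one window", call. = FALSE)
  if (!all(c("sample_id", "value") %in% names(samples))) {
    stop("samples must have columns sample_id and value", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = samples$sample_id,
                        value = samples$value)
  flags <- matrix(FALSE, nrow = nrow(out), ncol = nrow(windows))
  near <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    flags[, i] <- out$value < w$lower | out$value > w$upper
    near <- near | abs(out$value - w$lower) <= boundary_tol |
      abs(out$value - w$upper) <= boundary_tol
    out[[paste0("out_", w$method)]] <- flags[, i]
  }
  out$consensus_count <- as.integer(rowSums(flags))
  out$is_consensus_outlier <- out$consensus_count == nrow(windows)
  out$boundary <- near
  out
}

#' Summarize an outlier report
#'
#' Orders the per-sample report by consensus count, then by distance from
#' the (first) window center, and tabulates per-method outlier lists.
#'
#' @param report Tibble from [classify_outliers()].
#' @param windows The windows the report was built from (used for the
#'   centers).
#' @return List with `per_sample` (ordered report) and `per_method`
#'   (tibble: `method`, `n_flagged`, `flagged_ids`).
#' @export
consensus_summary <- function(report, windows) {
  center <- mean(windows$center)
  flag_cols <- grep("^out_", names(report), value = TRUE)
  if (nrow(report) == 0) {
    return(list(
      per_sample = report,
      per_method = tibble::tibble(method = sub("^out_", "", flag_cols),
                                  n_flagged = 0L, flagged_ids = "")
    ))
  }
  ord <- order(-report$consensus_count, -abs(report$value - center))
  per_method <- dplyr::bind_rows(lapply(flag_cols, function(col) {
    ids <- report$sample_id[report[[col]]]
    tibble::tibble(method = sub("^out_", "", col),
                   n_flagged = length(ids),
                   flagged_ids = paste(ids, collapse = ","))
  }))
  list(per_sample = report[ord, , drop = FALSE], per_method = per_method)
}
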