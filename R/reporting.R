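# Pipeline orchestration, figures, and machine-readable exports.
#
# Order of stages follows the analysis logic: validate -> convert ->
# describe -> pool -> screen -> compare with reference waters ->
# breastfeeding screen. Every report is regenerable from the exported
# TSV/JSON files alone.

#' Run the full palaeomobility pipeline
#'
#' Orchestrates the package over a sample table and site registry:
#' validation, scale conversion and drinking-water estimation, per-site
#' descriptive and robust statistics, pooling of tagged site groups
#' (poolability-tested), the n-gated four-criterion locality screen with
#' consensus outliers, reference-water verdicts and the breastfeeding
#' screen. The run is deterministic given its inputs and options.
#'
#' @param samples Sample tibble ([read_samples()] / [generate_scenario()]).
#' @param sites Site registry tibble ([read_site_config()] /
#'   [default_sites()]).
#' @param alpha Significance level for normality and poolability tests.
#' @param min_n Sample-size gate for the outlier screen (default 9).
#' @param methods Screen criteria (see [locality_windows()]).
#' @param mad_variant `"auto"`, `"norm"` or `"q3"`.
#' @param quantile_type Quantile rule (7 or 2).
#' @param boundary_tol Boundary annotation half-width, permil.
#' @param pool Pool tagged site groups before screening (default `TRUE`);
#'   pooled groups replace their member sites in the screen, as the
#'   members individually rarely pass the gate.
#' @return A list of artifacts: `validation`, `samples` (with
#'   `d18O_ca_vsmow` and `d18O_dw` columns added), `site_stats`,
#'   `spread`, `pooling`, `units` (screened analysis units), `screens`
#'   (per-unit windows + outlier report + consensus summary),
#'   `water_verdicts`, `breastfeeding`, `log`.
#' @export
run_pipeline <- function(samples, sites, alpha = 0.05, min_n = 9,
                         methods = c("two_sd", "mad", "tukey_iqr",
                                     "two_permil"),
                         mad_variant = c("auto", "norm", "q3"),
                         quantile_type = 7, boundary_tol = 0.05,
                         pool = TRUE) {
  mad_variant <- match.arg(mad_variant)
  validation <- validate_dataset(samples, sites)
  if (any(validation$severity == "error")) {
    stop("stage 'validate': dataset has blocking findings; ",
         "see validate_dataset()", call. = FALSE)
  }
  samples$d18O_ca_vsmow <- vpdb_to_vsmow(samples$d18O_ca_vpdb)
  samples$d18O_dw <- vsmow_to_drinking_water(samples$d18O_ca_vsmow)

  site_stats <- site_stats_table(samples, quantile_type)
  spread <- dplyr::bind_rows(lapply(unique(samples$site_code), function(code) {
    v <- samples$d18O_ca_vsmow[samples$site_code == code]
    if (length(v) < 2) return(NULL)
    dplyr::bind_cols(tibble::tibble(group = code),
                     robust_spread(v, quantile_type))
  }))

  # analysis units: pooled groups replace their members where poolable
  units <- list()
  pooling <- NULL
  pooled_members <- character()
  if (pool) {
    tags <- unique(stats::na.omit(sites$pooling_group))
    for (tag in tags) {
      pooled <- tryCatch(
        pool_sites(samples, sites, tag, alpha = alpha),
        error = function(e) e)
      if (inherits(pooled, "error")) {
        msg <- conditionMessage(pooled)
        pooling <- dplyr::bind_rows(pooling, tibble::tibble(
          group = tag, pooled = FALSE, note = msg))
        next
      }
      pooling <- dplyr::bind_rows(pooling, dplyr::bind_cols(
        tibble::tibble(group = tag), pooled$test[, c("test", "statistic",
                                                     "p", "pooled")]))
      pooled_members <- c(pooled_members, pooled$members)
      rng <- unique(stats::na.omit(
        sites$ref_water_lower[sites$code %in% pooled$members]))
      rng_hi <- unique(stats::na.omit(
        sites$ref_water_upper[sites$code %in% pooled$members]))
      units[[tag]] <- list(
        code = tag, samples = pooled$samples,
        ref = if (length(rng) == 1 && length(rng_hi) == 1) {
          c(rng, rng_hi)
        } else NULL)
    }
    if (!is.null(pooling)) {
      spread_pooled <- dplyr::bind_rows(lapply(units, function(u) {
        dplyr::bind_cols(tibble::tibble(group = u$code),
                         robust_spread(u$samples$d18O_ca_vsmow,
                                       quantile_type))
      }))
      spread <- dplyr::bind_rows(spread, spread_pooled)
    }
  }
  for (code in setdiff(unique(samples$site_code), pooled_members)) {
    site <- sites[sites$code == code, ]
    ref <- c(site$ref_water_lower, site$ref_water_upper)
    if (all(is.na(ref))) ref <- NULL
    units[[code]] <- list(code = code,
                          samples = samples[samples$site_code == code, ],
                          ref = ref)
  }

  screens <- list()
  water_verdicts <- NULL
  breastfeeding <- list()
  for (u in units) {
    v <- u$samples$d18O_ca_vsmow
    dw <- propagate_scale(mean(v),
                          if (length(v) > 1) stats::sd(v) else 0,
                          "vsmow_to_dw")
    water_verdicts <- dplyr::bind_rows(water_verdicts, dplyr::bind_cols(
      tibble::tibble(group = u$code, n = length(v)),
      compare_reference_water(dw$mean, dw$sd, u$ref)))
    if (u$code %in% unique(samples$site_code) &&
        any(u$samples$tooth_generation == "permanent")) {
      breastfeeding[[u$code]] <- breastfeeding_screen(u$samples)
    }
    if (!sample_size_gate(length(v), min_n)) {
      screens[[u$code]] <- list(code = u$code, n = length(v),
                                gated = TRUE)
      next
    }
    windows <- locality_windows(v, methods = methods,
                                mad_variant = mad_variant, alpha = alpha,
                                quantile_type = quantile_type)
    report <- classify_outliers(
      tibble::tibble(sample_id = u$samples$sample_id, value = v),
      windows, boundary_tol = boundary_tol)
    screens[[u$code]] <- list(
      code = u$code, n = length(v), gated = FALSE,
      normality = attr(windows, "normality"),
      windows = windows, report = report,
      summary = consensus_summary(report, windows))
  }

  list(
    validation = validation,
    samples = samples,
    site_stats = site_stats,
    spread = spread,
    pooling = pooling,
    units = names(units),
    screens = screens,
    water_verdicts = water_verdicts,
    breastfeeding = breastfeeding,
    log = list(constants = iso_constants(), alpha = alpha, min_n = min_n,
               methods = methods, mad_variant = mad_variant,
               quantile_type = quantile_type, boundary_tol = boundary_tol,
               n_samples = nrow(samples), timestamp = NULL)
  )
}

.site_order <- function(samples, sites) {
  codes <- unique(samples$site_code)
  lat <- sites$latitude[match(codes, sites$code)]
  if (all(is.na(lat))) codes else codes[order(-lat)]
}

#' Violin plot of per-community isotope distributions
#'
#' One violin per community with an embedded box (first to third
#' quartile), a median line, whiskers covering the non-outlier range, and
#' individual dots for box-plot outliers -- the conventional presentation
#' for community isotope distributions. Sites are ordered by decreasing
#' latitude when the registry carries coordinates, registry order
#' otherwise.
#'
#' @param samples Sample tibble.
#' @param sites Site registry tibble (ordering, period fill).
#' @param axis `"d18O"` (default; plotted on the V-SMOW scale) or
#'   `"d13C"`.
#' @param out Optional file path; when given the figure is also written
#'   (PNG/SVG by extension).
#' @return The ggplot object, invisibly when `out` is given.
#' @export
violin_plot <- function(samples, sites, axis = c("d18O", "d13C"),
                        out = NULL) {
  axis <- match.arg(axis)
  if (nrow(samples) == 0) stop("no samples to plot", call. = FALSE)
  df <- samples
  df$value <- if (axis == "d18O") {
    vpdb_to_vsmow(df$d18O_ca_vpdb)
  } else df$d13C_ca_vpdb
  df <- df[!is.na(df$value), ]
  df$site_code <- factor(df$site_code, levels = .site_order(df, sites))
  df$period <- sites$period[match(as.character(df$site_code), sites$code)]
  ylab <- if (axis == "d18O") {
    expression(delta^18 * O[ca] ~ "(‰ V-SMOW)")
  } else {
    expression(delta^13 * C[ca] ~ "(‰ V-PDB)")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$site_code,
                                        y = .data$value,
                                        fill = .data$period)) +
    ggplot2::geom_violin(trim = TRUE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = 16,
                          fill = "white") +
    ggplot2::scale_fill_manual(values = c(copper_age = "#d8c78e",
                                          neolithic = "#e08a2e"),
                               na.value = "grey80") +
    ggplot2::labs(x = NULL, y = ylab, fill = "period") +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 8, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Bivariate oxygen-carbon plot
#'
#' \eqn{\delta^{18}O} (V-SMOW, x) against \eqn{\delta^{13}C} (V-PDB, y),
#' coloured by site, with marker shape by period (dots for Copper Age,
#' diamonds for Neolithic) or, with `shape_by = "generation"`, by
#' deciduous/permanent tooth. Optional mixing endmembers are overlaid as
#' labelled crosses.
#'
#' @param samples Sample tibble.
#' @param sites Site registry tibble.
#' @param shape_by `"period"` (default) or `"generation"`.
#' @param endmembers Optional list of endmembers (each with `label`,
#'   `d13C`, `d18O` on V-SMOW).
#' @param out Optional output file path.
#' @return The ggplot object, invisibly when `out` is given.
#' @export
bivariate_plot <- function(samples, sites,
                           shape_by = c("period", "generation"),
                           endmembers = NULL, out = NULL) {
  shape_by <- match.arg(shape_by)
  df <- samples[!is.na(samples$d13C_ca_vpdb) &
                  !is.na(samples$d18O_ca_vpdb), ]
  n_dropped <- nrow(samples) - nrow(df)
  if (nrow(df) == 0) stop("no samples with both isotope values",
                          call. = FALSE)
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) without d13C excluded from the ",
            "bivariate plot")
  }
  df$d18O_ca_vsmow <- vpdb_to_vsmow(df$d18O_ca_vpdb)
  df$shape_var <- if (shape_by == "period") {
    sites$period[match(df$site_code, sites$code)]
  } else df$tooth_generation
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d18O_ca_vsmow,
                                        y = .data$d13C_ca_vpdb,
                                        colour = .data$site_code,
                                        shape = .data$shape_var)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = if (shape_by == "period") {
      c(copper_age = 16, neolithic = 18)
    } else c(permanent = 16, deciduous = 17), na.value = 15) +
    ggplot2::labs(x = expression(delta^18 * O[ca] ~ "(‰ V-SMOW)"),
                  y = expression(delta^13 * C[ca] ~ "(‰ V-PDB)"),
                  colour = "site", shape = shape_by) +
    ggplot2::theme_minimal()
  if (!is.null(endmembers)) {
    em <- dplyr::bind_rows(lapply(endmembers, function(e) {
      tibble::tibble(label = e$label %||% "endmember",
                     d18O_ca_vsmow = as.numeric(e[["d18O"]]),
                     d13C_ca_vpdb = as.numeric(e[["d13C"]]))
    }))
    p <- p +
      ggplot2::geom_point(data = em,
                          ggplot2::aes(x = .data$d18O_ca_vsmow,
                                       y = .data$d13C_ca_vpdb),
                          inherit.aes = FALSE, shape = 4, size = 4,
                          stroke = 1.5) +
      ggplot2::geom_text(data = em,
                         ggplot2::aes(x = .data$d18O_ca_vsmow,
                                      y = .data$d13C_ca_vpdb,
                                      label = .data$label),
                         inherit.aes = FALSE, vjust = -1, size = 3)
  }
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

.flatten_screens <- function(screens) {
  lapply(screens, function(s) {
    if (isTRUE(s$gated)) {
      return(list(group = s$code, n = s$n, gated = TRUE))
    }
    list(
      group = s$code, n = s$n, gated = FALSE,
      normality = if (!is.null(s$normality)) as.list(s$normality),
      windows = as.data.frame(s$windows),
      samples = as.data.frame(s$report),
      per_method = as.data.frame(s$summary$per_method)
    )
  })
}

#' Export pipeline reports to disk
#'
#' Writes the standard report set: `site_stats.tsv` (per-site summary on
#' both oxygen scales and carbon), `spread.tsv` (robust spread per
#' screened group), `outliers.json` (windows, per-sample flags,
#' consensus), `water_verdicts.tsv` and `run_log.json` (constants,
#' thresholds, options). Numeric TSV columns are written at full
#' precision with a one-decimal presentation column for the headline
#' means.
#'
#' @param run Artifact list from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_reports <- function(run, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character()
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
    paths <<- c(paths, path)
  }
  stats <- run$site_stats
  if (nrow(stats) > 0) {
    stats$d18O_vsmow_mean_1dp <- report_round(stats$d18O_vsmow_mean)
  }
  wtsv(stats, "site_stats.tsv")
  wtsv(run$spread, "spread.tsv")
  verdicts <- run$water_verdicts
  if (!is.null(verdicts) && nrow(verdicts) > 0) {
    verdicts$mean_dw_1dp <- report_round(verdicts$mean_dw)
  }
  wtsv(verdicts %||% tibble::tibble(), "water_verdicts.tsv")

  out_json <- file.path(out_dir, "outliers.json")
  jsonlite::write_json(.flatten_screens(run$screens), out_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- c(paths, out_json)
  log_json <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(run$log, log_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, log_json)
  invisible(paths)
}
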