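# Sample tables and the site registry.
#
# The canonical sample table is one row per analysed tooth:
#   sample_id, site_code, period, tooth_element, tooth_generation,
#   d18O_ca_vpdb, d13C_ca_vpdb
# Extra columns are carried through untouched. Values are kept at full
# precision; one-decimal rounding happens only in reports.

.SAMPLE_COLUMNS <- c("sample_id", "site_code", "period", "tooth_element",
                     "tooth_generation", "d18O_ca_vpdb", "d13C_ca_vpdb")
.REQUIRED_COLUMNS <- c("sample_id", "site_code", "d18O_ca_vpdb")
.PERIODS <- c("neolithic", "copper_age")
.GENERATIONS <- c("deciduous", "permanent")
.DELTA_BOUNDS <- c(-30, 10)

.read_delim_chr <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "\"",
                    comment.char = "")
}

.parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("column '%s': unparseable number '%s' at row %d",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read a per-individual tooth sample table
#'
#' Reads a delimited table (comma by default, tab for `.tsv`) with one row
#' per analysed tooth into the canonical sample tibble. Required columns are
#' `sample_id`, `site_code` and `d18O_ca_vpdb`; `d13C_ca_vpdb`, `period`,
#' `tooth_element` and `tooth_generation` are optional and filled with `NA`
#' when absent. When `tooth_generation` is missing it is inferred from the
#' tooth element name (a lowercase `"d"` prefix, e.g. `"dm2"`, marks a
#' deciduous tooth) and defaults to `"permanent"` otherwise; the inference
#' is surfaced later by [validate_dataset()].
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param sep Field separator; inferred from the file extension when `NULL`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(d18O_ca_vpdb = "d18O (VPDB)")`.
#' @return A tibble with the canonical columns (extra file columns are
#'   preserved after them).
#' @export
read_samples <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  raw <- .read_delim_chr(path, sep)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(.SAMPLE_COLUMNS, names(raw))) raw[[col]] <- NA_character_
  raw$d18O_ca_vpdb <- .parse_numeric_column(raw$d18O_ca_vpdb, "d18O_ca_vpdb")
  raw$d13C_ca_vpdb <- .parse_numeric_column(raw$d13C_ca_vpdb, "d13C_ca_vpdb")

  infer <- is.na(raw$tooth_generation)
  raw$tooth_generation[infer] <- ifelse(
    grepl("^d", raw$tooth_element[infer]), "deciduous", "permanent")
  attr_inferred <- raw$sample_id[infer & is.na(raw$tooth_element)]

  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw[, c(.SAMPLE_COLUMNS,
                                   setdiff(names(raw), .SAMPLE_COLUMNS))])
  attr(out, "generation_defaulted") <- attr_inferred
  out
}

#' Write a sample table to disk
#'
#' Inverse of [read_samples()]: writes the canonical sample tibble as
#' CSV/TSV (separator chosen from the extension) at full stored precision.
#'
#' @param samples Sample tibble.
#' @param path Output path; `.tsv` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  df <- as.data.frame(samples)
  attr(df, "generation_defaulted") <- NULL
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

.site_from_entry <- function(entry) {
  if (is.null(entry$code)) stop("site entry without a code", call. = FALSE)
  rng <- entry$reference_water_range
  if (!is.null(rng)) {
    rng <- as.numeric(unlist(rng))
    if (length(rng) != 2 || any(!is.finite(rng))) {
      stop("site ", entry$code, ": reference_water_range must be two numbers",
           call. = FALSE)
    }
    if (rng[1] > rng[2]) {
      stop("site ", entry$code, ": reference_water_range lower > upper",
           call. = FALSE)
    }
  } else {
    rng <- c(NA_real_, NA_real_)
  }
  tibble::tibble(
    code = as.character(entry$code),
    name = as.character(entry$name %||% entry$code),
    period = as.character(entry$period %||% NA_character_),
    ref_water_lower = rng[1],
    ref_water_upper = rng[2],
    pooling_group = as.character(entry$pooling_group %||% NA_character_),
    latitude = as.numeric(entry$latitude %||% NA_real_)
  )
}

#' Read a site registry from YAML or JSON
#'
#' The registry describes each funerary community: its code, name, period,
#' an optional modern reference drinking-water \eqn{\delta^{18}O} range
#' (permil V-SMOW), an optional pooling group tag for communities close
#' enough to analyse jointly, and an optional latitude used to order plots.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` registry. The expected
#'   top level is a `sites:` list (or a bare list) of per-site maps with
#'   keys `code`, `name`, `period`, `reference_water_range`,
#'   `pooling_group`, `latitude`.
#' @return A tibble with columns `code`, `name`, `period`,
#'   `ref_water_lower`, `ref_water_upper`, `pooling_group`, `latitude`.
#' @seealso [default_sites()] for the bundled registry of the ten Italian
#'   Neolithic and Copper Age sites.
#' @export
read_site_config <- function(path) {
  if (!file.exists(path)) stop("site config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- cfg$sites %||% cfg
  if (length(entries) == 0) stop("site config is empty: ", path, call. = FALSE)
  out <- dplyr::bind_rows(lapply(entries, .site_from_entry))
  dup <- out$code[duplicated(out$code)]
  if (length(dup) > 0) {
    stop("duplicate site code: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Bundled registry of the ten studied sites
#'
#' Loads the packaged registry covering two Neolithic (MC, PA) and eight
#' Copper Age (SS, FR, CE, OC, CM, TC, PB, GN) Italian funerary
#' communities, including the published modern drinking-water reference
#' ranges where available and the `rome_copper_age` pooling group
#' (OC, CM, TC, PB).
#'
#' @return Site registry tibble (see [read_site_config()]).
#' @export
default_sites <- function() {
  read_site_config(system.file("extdata", "sites.yaml", package = "isomob"))
}

#' Published per-site summary statistics
#'
#' Descriptive statistics (n, min, max, mean, sd) reported for the ten
#' communities on both oxygen scales and for carbon, as transcribed from
#' the published community table. These figures parameterize the bundled
#' synthetic scenario and the conversion fidelity checks.
#'
#' @return Tibble with one row per site.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "site_summary.tsv", package = "isomob")
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Published robust spread measures per community
#'
#' The reported "modifying values" (IQR, raw MAD, normal-consistent MAD,
#' MAD-Q3) for the communities that passed the sample-size gate; `NA`
#' marks values not reported for a community (the MAD variant not selected
#' by its normality test).
#'
#' @return Tibble with columns `group`, `iqr`, `mad_raw`, `mad_norm`,
#'   `mad_q3`.
#' @export
reference_spread <- function() {
  path <- system.file("extdata", "site_spread.tsv", package = "isomob")
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Validate a sample table against the site registry
#'
#' Reporting-only check of the dataset invariants: every `site_code`
#' resolves in the registry, delta values fall within plausible bounds
#' (-30 to +10 permil), `sample_id` is unique, periods and tooth
#' generations use known levels, and \eqn{\delta^{18}O} is present for
#' every sample (it drives the whole mobility analysis). Missing
#' \eqn{\delta^{13}C} is allowed but flagged at `"warning"` severity.
#'
#' @param samples Sample tibble from [read_samples()] or
#'   [generate_scenario()].
#' @param sites Site registry tibble.
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"warning"`), `check`, `sample_id`, `message`; zero rows at
#'   `"error"` severity means the dataset satisfies all invariants.
#' @export
validate_dataset <- function(samples, sites) {
  finding <- function(severity, check, sample_id, message) {
    tibble::tibble(severity = severity, check = check,
                   sample_id = sample_id, message = message)
  }
  out <- list()

  unknown <- !samples$site_code %in% sites$code
  if (any(unknown)) {
    out[[length(out) + 1]] <- finding(
      "error", "unknown_site", samples$sample_id[unknown],
      paste0("site code '", samples$site_code[unknown],
             "' not in the registry"))
  }
  dup <- duplicated(samples$sample_id)
  if (any(dup)) {
    out[[length(out) + 1]] <- finding(
      "error", "duplicate_id", samples$sample_id[dup], "duplicate sample_id")
  }
  for (col in c("d18O_ca_vpdb", "d13C_ca_vpdb")) {
    v <- samples[[col]]
    oob <- !is.na(v) & (v < .DELTA_BOUNDS[1] | v > .DELTA_BOUNDS[2])
    if (any(oob)) {
      out[[length(out) + 1]] <- finding(
        "error", "out_of_range", samples$sample_id[oob],
        sprintf("%s = %g outside [%g, %g] permil", col, v[oob],
                .DELTA_BOUNDS[1], .DELTA_BOUNDS[2]))
    }
  }
  no_o <- is.na(samples$d18O_ca_vpdb)
  if (any(no_o)) {
    out[[length(out) + 1]] <- finding(
      "error", "missing_d18O", samples$sample_id[no_o],
      "missing d18O; sample cannot enter the mobility analysis")
  }
  no_c <- is.na(samples$d13C_ca_vpdb)
  if (any(no_c)) {
    out[[length(out) + 1]] <- finding(
      "warning", "missing_d13C", samples$sample_id[no_c],
      "missing d13C; excluded from carbon-based screens only")
  }
  bad_period <- !is.na(samples$period) & !samples$period %in% .PERIODS
  if (any(bad_period)) {
    out[[length(out) + 1]] <- finding(
      "error", "unknown_period", samples$sample_id[bad_period],
      paste0("period '", samples$period[bad_period], "' not one of ",
             paste(.PERIODS, collapse = "/")))
  }
  bad_gen <- !is.na(samples$tooth_generation) &
    !samples$tooth_generation %in% .GENERATIONS
  if (any(bad_gen)) {
    out[[length(out) + 1]] <- finding(
      "error", "unknown_generation", samples$sample_id[bad_gen],
      paste0("tooth_generation '", samples$tooth_generation[bad_gen], "'"))
  }
  defaulted <- attr(samples, "generation_defaulted")
  if (length(defaulted) > 0) {
    out[[length(out) + 1]] <- finding(
      "warning", "generation_defaulted", defaulted,
      "tooth_generation defaulted to 'permanent' (no element name)")
  }
  if (length(out) == 0) {
    return(finding(character(), character(), character(), character()))
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
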