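# Compatibility of a community's estimated drinking water with modern
# reference waters, a breastfeeding-enrichment screen for early-forming
# teeth, and a two-endmember mixing diagnostic for diagenetic carbonate
# contamination.

#' Compare estimated drinking water with a reference range
#'
#' A community is `"consistent"` with local waters when the interval
#' `mean_dw +/- sd_dw` (closed) overlaps the reference range; otherwise
#' the verdict is `"below"` or `"above"` by which side the mean falls on.
#' Reference endpoints are normalized on entry, so a reversed range gives
#' identical verdicts; a missing range yields `"no_reference"`.
#'
#' @param mean_dw,sd_dw Estimated drinking-water \eqn{\delta^{18}O} mean
#'   and standard deviation, permil V-SMOW (see
#'   [vsmow_to_drinking_water()], [propagate_scale()]). `sd_dw = 0`
#'   compares the mean alone.
#' @param ref Numeric length-2 reference range (permil V-SMOW), or `NULL`
#'   / `NA` when no reference exists for the area.
#' @return A one-row tibble: `mean_dw`, `sd_dw`, `ref_lower`, `ref_upper`,
#'   `verdict`.
#' @export
#' @examples
#' compare_reference_water(-6.0, 0.9, c(-6, -5))  # consistent
#' compare_reference_water(-8.3, 1.1, c(-7, -6))  # below
compare_reference_water <- function(mean_dw, sd_dw, ref) {
  if (is.null(ref) || all(is.na(ref))) {
    return(tibble::tibble(mean_dw = mean_dw, sd_dw = sd_dw,
                          ref_lower = NA_real_, ref_upper = NA_real_,
                          verdict = "no_reference"))
  }
  if (length(ref) != 2 || any(!is.finite(ref))) {
    stop("ref must be two finite numbers or NULL", call. = FALSE)
  }
  ref <- sort(ref)
  if (sd_dw < 0) stop("sd_dw must be non-negative", call. = FALSE)
  lo <- mean_dw - sd_dw
  hi <- mean_dw + sd_dw
  verdict <- if (hi >= ref[1] && lo <= ref[2]) {
    "consistent"
  } else if (mean_dw < ref[1]) "below" else "above"
  tibble::tibble(mean_dw = mean_dw, sd_dw = sd_dw,
                 ref_lower = ref[1], ref_upper = ref[2], verdict = verdict)
}

#' Screen deciduous teeth for breastfeeding enrichment
#'
#' Teeth mineralized before weaning can be enriched in 18-O by roughly
#' 0.5-2 permil relative to permanent teeth of the same community. The
#' screen compares each deciduous value with the permanent min-max range
#' and estimates the mean deciduous-minus-permanent offset; systematic
#' enrichment is flagged only when that offset falls in the expected
#' 0.5-2 permil band *and* every deciduous value exceeds the permanent
#' median (a one-sided shift, not mere scatter).
#'
#' @param samples Sample tibble for one community with columns
#'   `sample_id`, `tooth_generation`, and the value column.
#' @param value_col Column screened (default the measured V-PDB oxygen;
#'   the offset is scale-dependent only through the V-PDB/V-SMOW slope,
#'   which is ~1).
#' @param band Expected enrichment band, permil (default `c(0.5, 2)`).
#' @return A list: `n_deciduous`, `n_permanent`, `offset` (deciduous mean
#'   minus permanent mean), `within_adult_range` (logical per deciduous
#'   sample), `systematic_enrichment`. With no deciduous teeth the list
#'   has `n_deciduous = 0` and `NA` fields (an empty screen, not an
#'   error).
#' @export
breastfeeding_screen <- function(samples, value_col = "d18O_ca_vpdb",
                                 band = c(0.5, 2)) {
  gen <- samples$tooth_generation
  perm <- samples[[value_col]][gen == "permanent"]
  perm <- perm[!is.na(perm)]
  dec <- samples[[value_col]][gen == "deciduous"]
  dec <- dec[!is.na(dec)]
  if (length(perm) == 0) {
    stop("breastfeeding screen needs at least one permanent tooth",
         call. = FALSE)
  }
  if (length(dec) == 0) {
    return(list(n_deciduous = 0L, n_permanent = length(perm),
                offset = NA_real_, within_adult_range = logical(),
                systematic_enrichment = NA))
  }
  offset <- mean(dec) - mean(perm)
  within <- dec >= min(perm) & dec <= max(perm)
  systematic <- offset >= band[1] && offset <= band[2] &&
    all(dec > stats::median(perm))
  list(n_deciduous = length(dec), n_permanent = length(perm),
       offset = offset, within_adult_range = within,
       systematic_enrichment = systematic)
}

#' Two-endmember mixing diagnostic for diagenetic contamination
#'
#' Post-mortem exchange with cave carbonate pulls a tooth's composition
#' along the line joining its biogenic value to the secondary-carbonate
#' endmember (e.g. a speleothem). For each sample the apparent mixing
#' fraction is solved on the carbon axis,
#' `f = (d13C - d13C_b) / (d13C_a - d13C_b)` (so `f = 1` at endmember A),
#' together with the perpendicular distance to the A-B segment in
#' standardized (d13C, d18O) space. The diagnostic never alters or
#' excludes measurements; it only reports which samples lie between the
#' endmembers and how close to the mixing line they sit.
#'
#' @param samples Sample tibble with `sample_id`, `d13C_ca_vpdb` and a
#'   `d18O` column on the V-SMOW scale (`d18O_ca_vsmow`; computed from
#'   V-PDB when absent).
#' @param end_a,end_b Endmembers: lists or named vectors with elements
#'   `d13C` (permil V-PDB) and `d18O` (permil V-SMOW); must differ in
#'   `d13C`.
#' @return Tibble: `sample_id`, `f`, `distance` (standardized units),
#'   `between_endmembers` (`0 <= f <= 1`).
#' @export
mixing_check <- function(samples, end_a, end_b) {
  a <- c(d13C = as.numeric(end_a[["d13C"]]), d18O = as.numeric(end_a[["d18O"]]))
  b <- c(d13C = as.numeric(end_b[["d13C"]]), d18O = as.numeric(end_b[["d18O"]]))
  if (any(!is.finite(c(a, b)))) stop("endmembers must be finite", call. = FALSE)
  if (a[["d13C"]] == b[["d13C"]]) {
    stop("endmembers coincide in d13C; mixing fraction is unidentifiable",
         call. = FALSE)
  }
  d13C <- samples$d13C_ca_vpdb
  d18O <- if ("d18O_ca_vsmow" %in% names(samples)) {
    samples$d18O_ca_vsmow
  } else {
    vpdb_to_vsmow(samples$d18O_ca_vpdb)
  }
  f <- (d13C - b[["d13C"]]) / (a[["d13C"]] - b[["d13C"]])

  # standardize both axes by the endmember separation so the distance is
  # invariant to affine rescaling of either axis
  sx <- abs(a[["d13C"]] - b[["d13C"]])
  sy <- abs(a[["d18O"]] - b[["d18O"]])
  if (sy == 0) sy <- 1  # endmembers level in d18O: distance is pure d18O offset
  p <- cbind((d13C - b[["d13C"]]) / sx, (d18O - b[["d18O"]]) / sy)
  ab <- c((a[["d13C"]] - b[["d13C"]]) / sx, (a[["d18O"]] - b[["d18O"]]) / sy)
  tproj <- pmin(1, pmax(0, (p %*% ab) / sum(ab^2)))
  foot <- cbind(tproj * ab[1], tproj * ab[2])
  distance <- sqrt(rowSums((p - foot)^2))
  tibble::tibble(sample_id = samples$sample_id, f = f,
                 distance = as.numeric(distance),
                 between_endmembers = f >= 0 & f <= 1)
}
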