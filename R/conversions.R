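# Linear transfer functions between isotope scales.
#
# Enamel carbonate delta values are measured against V-PDB; comparison with
# environmental waters requires the V-SMOW scale and a carbonate-to-drinking-
# water transfer function. Both maps are affine, so location statistics move
# through them directly and spread statistics scale by |slope|.

.ISO_CONSTANTS <- list(
  vpdb_to_vsmow = list(slope = 1.03091, intercept = 30.91),
  vsmow_to_dw   = list(slope = 1.59, intercept = -48.634)
)

#' Conversion constants used by the isotope scale maps
#'
#' Returns the fixed coefficients of the two affine maps used throughout the
#' package: the IUPAC-recommended V-PDB to V-SMOW conversion
#' (`1.03091 * x + 30.91`) and the enamel-carbonate-to-drinking-water
#' transfer function (`1.59 * x - 48.634`, Chenery-style calibration).
#' The constants are exposed for provenance logging; the conversion
#' functions do not take them as arguments, so they cannot be silently
#' overridden mid-analysis.
#'
#' @return A named list with components `vpdb_to_vsmow` and `vsmow_to_dw`,
#'   each a list with elements `slope` and `intercept`.
#' @export
#' @examples
#' iso_constants()
iso_constants <- function() .ISO_CONSTANTS

.check_finite <- function(x, what = "input") {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Convert enamel carbonate \eqn{\delta^{18}O} from V-PDB to V-SMOW
#'
#' Applies the affine scale conversion
#' \eqn{\delta^{18}O_{SMOW} = 1.03091\,\delta^{18}O_{PDB} + 30.91}.
#'
#' @param x Numeric vector of \eqn{\delta^{18}O} values, permil V-PDB.
#' @return Numeric vector, permil V-SMOW, at full precision.
#' @seealso [vsmow_to_vpdb()] for the inverse, [report_round()] for the
#'   one-decimal presentation used in reports.
#' @export
#' @examples
#' vpdb_to_vsmow(-4.0) # 26.786, reported as 26.8
vpdb_to_vsmow <- function(x) {
  .check_finite(x, "d18O (V-PDB)")
  k <- .ISO_CONSTANTS$vpdb_to_vsmow
  k[["slope"]] * x + k[["intercept"]]
}

#' Convert \eqn{\delta^{18}O} from V-SMOW back to V-PDB
#'
#' Exact algebraic inverse of [vpdb_to_vsmow()].
#'
#' @param x Numeric vector of \eqn{\delta^{18}O} values, permil V-SMOW.
#' @return Numeric vector, permil V-PDB.
#' @export
vsmow_to_vpdb <- function(x) {
  .check_finite(x, "d18O (V-SMOW)")
  k <- .ISO_CONSTANTS$vpdb_to_vsmow
  (x - k[["intercept"]]) / k[["slope"]]
}

#' Estimate drinking-water \eqn{\delta^{18}O} from enamel carbonate
#'
#' Applies the linear carbonate-to-drinking-water transfer function
#' \eqn{\delta^{18}O_{dw} = 1.59\,\delta^{18}O_{SMOW} - 48.634}. The input
#' must already be on the V-SMOW scale (use [vpdb_to_vsmow()] first).
#'
#' @param x Numeric vector of enamel carbonate \eqn{\delta^{18}O}, permil
#'   V-SMOW.
#' @return Numeric vector of estimated drinking-water \eqn{\delta^{18}O},
#'   permil V-SMOW.
#' @export
#' @examples
#' vsmow_to_drinking_water(26.8) # -6.022, reported as -6.0
vsmow_to_drinking_water <- function(x) {
  .check_finite(x, "d18O (V-SMOW)")
  k <- .ISO_CONSTANTS$vsmow_to_dw
  k[["slope"]] * x + k[["intercept"]]
}

#' Propagate a mean and standard deviation through a scale conversion
#'
#' For an affine map `a*x + b` the mean transforms as `a*mean + b` and the
#' standard deviation as `|a| * sd`, which is how "mean +/- sd" summaries
#' are reported on converted scales.
#'
#' @param mean Numeric scalar, permil on the source scale.
#' @param sd Non-negative numeric scalar, permil.
#' @param transform One of `"vpdb_to_vsmow"`, `"vsmow_to_vpdb"`,
#'   `"vsmow_to_dw"`.
#' @return Named list with elements `mean` and `sd` on the target scale.
#' @export
#' @examples
#' propagate_scale(26.8, 0.6, "vsmow_to_dw") # mean -6.022, sd 0.954
propagate_scale <- function(mean, sd,
                            transform = c("vpdb_to_vsmow", "vsmow_to_vpdb",
                                          "vsmow_to_dw")) {
  transform <- match.arg(transform)
  .check_finite(mean, "mean")
  .check_finite(sd, "sd")
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  fun <- switch(transform,
    vpdb_to_vsmow = vpdb_to_vsmow,
    vsmow_to_vpdb = vsmow_to_vpdb,
    vsmow_to_dw   = vsmow_to_drinking_water
  )
  slope <- switch(transform,
    vpdb_to_vsmow = .ISO_CONSTANTS$vpdb_to_vsmow[["slope"]],
    vsmow_to_vpdb = 1 / .ISO_CONSTANTS$vpdb_to_vsmow[["slope"]],
    vsmow_to_dw   = .ISO_CONSTANTS$vsmow_to_dw[["slope"]]
  )
  list(mean = fun(mean), sd = abs(slope) * sd)
}

#' Round for presentation, half away from zero
#'
#' Delta values are conventionally presented at one decimal. Base R's
#' `round()` rounds half to even; isotope tables round half away from zero
#' (so -6.05 prints as -6.1, not -6.0). All internal computation stays at
#' full precision; this function is applied only when formatting output.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
report_round <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
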