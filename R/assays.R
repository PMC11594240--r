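#' Linear standard curve for the TBARS colorimetric assay
#'
#' Maps absorbance at 532 nm to malondialdehyde (MDA) concentration via an
#' affine calibration. Curve parameters come from the user's own standard
#' series; they are never assumed.
#'
#' @param slope (ug/mL) per absorbance unit; must be > 0.
#' @param intercept ug/mL.
#' @param wavelength Informational wavelength in nm; default 532.
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept = 0, wavelength = 532) {
  if (!is.numeric(slope) || slope <= 0)
    stop("'slope' must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 wavelength = wavelength),
            class = "standard_curve")
}

#' MDA concentration from absorbance
#'
#' Evaluates the standard curve and clamps negative predictions to zero
#' (an absorbance below the curve's x-intercept reads as no analyte); the
#' clamp is reported with a warning.
#'
#' @param curve A [standard_curve()].
#' @param absorbance Non-negative absorbance reading(s); vectorized.
#' @return Concentration(s) in ug/mL.
#' @export
concentration_from_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(absorbance < 0)) stop("'absorbance' must be >= 0", call. = FALSE)
  conc <- curve$slope * absorbance + curve$intercept
  if (any(conc < 0)) {
    warning("negative concentration(s) clamped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' TBARS value from concentration, volume and mass
#'
#' TBARS (mg MDA/kg) = c x V x 1000 / (m x 1000) = c V / m, with c the MDA
#' concentration of the sample solution (ug/mL), V the constant volume of
#' the solution (mL) and m the sample mass (g). The factor-of-1000 pair
#' cancels: ug/g is identically mg/kg.
#'
#' @param c MDA concentration in ug/mL, >= 0.
#' @param V Constant volume of sample solution in mL, > 0. What counts as
#'   the "constant volume" depends on the extraction protocol and must be
#'   supplied by the analyst.
#' @param m Sample mass in g, > 0.
#' @return TBARS value in mg MDA/kg.
#' @examples
#' tbars_value(0.05, 100, 10)  # 0.5 mg MDA/kg, the usual spoilage limit
#' @export
tbars_value <- function(c, V, m) {
  if (any(V <= 0)) stop("'V' must be > 0", call. = FALSE)
  if (any(m <= 0)) stop("'m' must be > 0", call. = FALSE)
  if (any(c < 0)) stop("'c' must be >= 0", call. = FALSE)
  c * V * 1000 / (m * 1000)
}

#' TVB-N freshness classification
#'
#' Total volatile basic nitrogen below 15 mg/100 g indicates a fresh
#' sample, 15-30 mg/100 g (inclusive at both ends) incipient spoilage, and
#' above 30 mg/100 g a spoiled sample.
#'
#' @param value TVB-N in mg per 100 g, >= 0; vectorized.
#' @return Factor with levels `fresh`, `incipient_spoilage`, `spoiled`
#'   (ordered), same length as `value`.
#' @examples
#' classify_tvbn(c(10, 15, 30, 30.01))
#' @export
classify_tvbn <- function(value) {
  if (any(value < 0)) stop("TVB-N value must be >= 0", call. = FALSE)
  cls <- ifelse(value < 15, "fresh",
                ifelse(value <= 30, "incipient_spoilage", "spoiled"))
  factor(cls, levels = c("fresh", "incipient_spoilage", "spoiled"),
         ordered = TRUE)
}

# Rubric bands for the three sensory attributes (points).
.sensory_bands <- list(color = c(10, 30), fragrance = c(20, 40),
                       tissue = c(10, 30))

#' Compose a total sensory score from attribute scores
#'
#' The sensory rubric scores color out of 30 (band 10-30), fragrance out
#' of 40 (band 20-40) and tissue out of 30 (band 10-30); the total is
#' their sum, between 40 and 100 points.
#'
#' @param color,fragrance,tissue Attribute scores within their rubric
#'   bands.
#' @return An object of class `sensory_score` with the three components
#'   and their `total`.
#' @examples
#' total_sensory(26, 36, 26)$total  # 88
#' @export
total_sensory <- function(color, fragrance, tissue) {
  comps <- list(color = color, fragrance = fragrance, tissue = tissue)
  for (nm in names(comps)) {
    band <- .sensory_bands[[nm]]
    v <- comps[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < band[1] || v > band[2])
      stop(sprintf("'%s' must lie in the rubric band [%g, %g]",
                   nm, band[1], band[2]), call. = FALSE)
  }
  structure(list(color = color, fragrance = fragrance, tissue = tissue,
                 total = color + fragrance + tissue),
            class = "sensory_score")
}

#' @export
print.sensory_score <- function(x, ...) {
  cat(sprintf("<sensory_score> total %g (color %g, fragrance %g, tissue %g)\n",
              x$total, x$color, x$fragrance, x$tissue))
  invisible(x)
}
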