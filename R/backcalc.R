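#' Body-proportional back-calculation parameters
#'
#' The four constants of the body-proportional-hypothesis (BPH)
#' back-calculation equation relating humerus diameter to straightline
#' carapace length (SCL) in Hawaiian green turtles:
#' \deqn{L = [L_{op} + b (D - D_{op})^c] \cdot L_{final} /
#'       [L_{op} + b (D_{final} - D_{op})^c]}
#' where \eqn{L_{op}} is the average hatchling SCL, \eqn{D_{op}} the minimum
#' hatchling humerus diameter, \eqn{b} the allometric slope and \eqn{c} the
#' proportionality coefficient.  Defaults are the published constants for
#' Hawaiian green turtles (36.4--97.9 cm SCL).
#'
#' @param hatchling_length_cm Average hatchling SCL \eqn{L_{op}} (cm).
#' @param hatchling_diameter_mm Minimum hatchling humerus diameter
#'   \eqn{D_{op}} (mm).
#' @param slope Allometric slope \eqn{b} (cm per mm^c).
#' @param exponent Proportionality coefficient \eqn{c} (dimensionless).
#' @return An object of class \code{bph_params}.
#' @examples
#' bph_params()
#' @export
bph_params <- function(hatchling_length_cm = 5.1,
                       hatchling_diameter_mm = 2.6,
                       slope = 3.127,
                       exponent = 0.928) {
  if (!is.numeric(hatchling_length_cm) || hatchling_length_cm <= 0)
    stop("hatchling_length_cm (L_op) must be > 0")
  if (!is.numeric(hatchling_diameter_mm) || hatchling_diameter_mm <= 0)
    stop("hatchling_diameter_mm (D_op) must be > 0")
  if (!is.numeric(slope) || slope <= 0)
    stop("slope (b) must be > 0")
  if (!is.numeric(exponent) || exponent <= 0 || exponent > 2)
    stop("exponent (c) must be in (0, 2]")
  structure(
    list(l_op = as.numeric(hatchling_length_cm),
         d_op = as.numeric(hatchling_diameter_mm),
         b = as.numeric(slope),
         c = as.numeric(exponent)),
    class = "bph_params")
}

#' @export
print.bph_params <- function(x, ...) {
  cat("Body-proportional back-calculation parameters\n")
  cat(sprintf("  hatchling SCL (L_op): %.3g cm\n", x$l_op))
  cat(sprintf("  hatchling humerus diameter (D_op): %.3g mm\n", x$d_op))
  cat(sprintf("  allometric slope (b): %.4g\n", x$b))
  cat(sprintf("  proportionality coefficient (c): %.4g\n", x$c))
  invisible(x)
}

# L_op + b (D - D_op)^c, the mean allometric SCL at humerus diameter D
bph_allometry <- function(d_mm, params) {
  params$l_op + params$b * (d_mm - params$d_op)^params$c
}

#' Back-calculate carapace length from a growth-mark diameter
#'
#' Applies the BPH equation: the SCL at the time a growth mark of diameter
#' \code{d_mm} was deposited, anchored by the final section diameter and the
#' SCL measured at dead recovery.  The equation is exact at the section edge
#' (\code{d_mm == d_final_mm} returns \code{l_final_cm}), strictly
#' increasing in \code{d_mm}, and proportional in \code{l_final_cm}.
#'
#' @param d_mm Mark diameter of interest (mm); may be a vector.  Must lie in
#'   \code{[params$d_op, d_final_mm]}; extrapolation beyond the section edge
#'   is an error.
#' @param d_final_mm Humerus cross-section diameter at recovery (mm).
#' @param l_final_cm SCL measured at dead recovery (cm).
#' @param params A \code{\link{bph_params}} object.
#' @return Estimated SCL (cm), same length as \code{d_mm}.
#' @examples
#' back_calculate_length(20, 25, 60)    # SCL when the humerus was 20 mm
#' back_calculate_length(25, 25, 60)    # == 60 at the section edge
#' @export
back_calculate_length <- function(d_mm, d_final_mm, l_final_cm,
                                  params = bph_params()) {
  stopifnot(inherits(params, "bph_params"))
  if (!is.numeric(l_final_cm) || length(l_final_cm) != 1 || l_final_cm <= 0)
    stop("l_final_cm must be a single positive SCL (cm)")
  if (!is.numeric(d_final_mm) || length(d_final_mm) != 1 ||
      d_final_mm <= params$d_op)
    stop("d_final_mm must exceed the hatchling diameter D_op")
  if (any(d_mm < params$d_op - 1e-9))
    stop(sprintf("mark diameter below hatchling diameter D_op = %g mm",
                 params$d_op))
  if (any(d_mm > d_final_mm + 1e-9))
    stop(sprintf(
      "mark diameter exceeds section diameter D_final = %g mm (no extrapolation)",
      d_final_mm))
  d_mm <- pmin(pmax(d_mm, params$d_op), d_final_mm)
  bph_allometry(d_mm, params) * l_final_cm / bph_allometry(d_final_mm, params)
}

#' Invert the BPH equation: diameter at which a given SCL was attained
#'
#' Analytic inverse of \code{\link{back_calculate_length}}.  Used by the
#' growth simulator and to reconstruct mark diameters from published SCL
#' estimates.
#'
#' @param l_cm Target SCL (cm); may be a vector.  Must lie in the attainable
#'   interval \code{[back_calculate_length(params$d_op, ...), l_final_cm]}.
#' @inheritParams back_calculate_length
#' @return Mark diameter (mm) such that back-calculation returns
#'   \code{l_cm}.
#' @export
invert_length_to_diameter <- function(l_cm, d_final_mm, l_final_cm,
                                      params = bph_params()) {
  stopifnot(inherits(params, "bph_params"))
  if (!is.numeric(l_final_cm) || length(l_final_cm) != 1 || l_final_cm <= 0)
    stop("l_final_cm must be a single positive SCL (cm)")
  lo <- back_calculate_length(params$d_op, d_final_mm, l_final_cm, params)
  if (any(l_cm < lo - 1e-9))
    stop(sprintf("SCL below the hatchling-diameter image (%.6g cm)", lo))
  if (any(l_cm > l_final_cm + 1e-9))
    stop("SCL exceeds the final SCL; diameter would extrapolate beyond the section")
  l_cm <- pmin(pmax(l_cm, lo), l_final_cm)
  denom <- bph_allometry(d_final_mm, params)
  # solve l = (l_op + b (d - d_op)^c) * l_final / denom for d
  core <- (l_cm * denom / l_final_cm - params$l_op) / params$b
  core <- pmax(core, 0)
  params$d_op + core^(1 / params$c)
}

#' Back-calculated growth history and annual somatic growth rates
#'
#' Back-calculates one SCL per (collapsed) LAG via the BPH equation and
#' derives annual somatic growth rates as differences between SCLs
#' back-calculated for consecutive calendar years.  Gaps in the year
#' sequence produce no rate entry.
#'
#' @param profile A \code{\link{bone_profile}}; its LAG diameters must
#'   already be collapsed (one diameter per annual mark).
#' @param years Integer vector of calendar years, aligned 1:1 with the
#'   collapsed LAG diameters (innermost to outermost).
#' @param record The matching \code{\link{turtle_record}} (supplies the
#'   anchoring SCL at recovery).
#' @param params A \code{\link{bph_params}} object.
#' @return An object of class \code{growth_history}: list with
#'   \code{turtle_id}, \code{entries} (data frame \code{year},
#'   \code{scl_cm}) and \code{rates} (data frame \code{from_year},
#'   \code{to_year}, \code{rate_cm_per_yr}).
#' @export
growth_history <- function(profile, years, record, params = bph_params()) {
  stopifnot(inherits(profile, "bone_profile"),
            inherits(record, "turtle_record"))
  diams <- collapse_double_lags(profile$lag_diameters, profile$double_flags)
  if (length(years) != length(diams))
    stop(sprintf("years (%d) and collapsed LAGs (%d) are misaligned",
                 length(years), length(diams)))
  scl <- back_calculate_length(diams, profile$section_diameter,
                               record$scl_at_recovery, params)
  entries <- data.frame(year = as.integer(years), scl_cm = scl)
  consec <- which(diff(entries$year) == 1L)
  rates <- data.frame(
    from_year = entries$year[consec],
    to_year = entries$year[consec + 1L],
    rate_cm_per_yr = entries$scl_cm[consec + 1L] - entries$scl_cm[consec])
  structure(list(turtle_id = record$id, entries = entries, rates = rates),
            class = "growth_history")
}

#' @export
print.growth_history <- function(x, ...) {
  cat(sprintf("Growth history for %s: %d back-calculated SCLs\n",
              x$turtle_id, nrow(x$entries)))
  print(transform(x$entries, scl_cm = round(scl_cm, 1)), row.names = FALSE)
  if (nrow(x$rates)) {
    cat("Annual growth rates (cm/yr):\n")
    print(transform(x$rates, rate_cm_per_yr = round(rate_cm_per_yr, 2)),
          row.names = FALSE)
  }
  invisible(x)
}
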