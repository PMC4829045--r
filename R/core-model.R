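#' One turtle's capture/tagging/OTC/stranding history
#'
#' @param id Turtle identifier (e.g. \code{"CM-12"}).
#' @param date_tagged Calendar date of tagging and SCL measurement.
#' @param scl_at_tagging SCL measured at tagging (cm).
#' @param date_stranded Date of stranding / dead recovery.
#' @param scl_at_recovery SCL measured at recovery (cm); the anchoring
#'   \eqn{L_{final}} of the BPH equation.
#' @param date_otc Optional date of oxytetracycline injection.
#' @param fibropapilloma Logical; fibropapilloma tumours present.
#' @return An object of class \code{turtle_record}.
#' @export
turtle_record <- function(id, date_tagged, scl_at_tagging,
                          date_stranded, scl_at_recovery,
                          date_otc = NULL, fibropapilloma = FALSE) {
  rec <- structure(
    list(id = as.character(id),
         date_tagged = as.Date(date_tagged),
         scl_at_tagging = as.numeric(scl_at_tagging),
         date_otc = if (is.null(date_otc) || all(is.na(date_otc))) NULL
                    else as.Date(date_otc),
         date_stranded = as.Date(date_stranded),
         scl_at_recovery = as.numeric(scl_at_recovery),
         fibropapilloma = isTRUE(fibropapilloma)),
    class = "turtle_record")
  rec
}

#' Ordered LAG measurements from one humerus cross-section
#'
#' Diameters are measured along an axis parallel to the dorsal edge of the
#' section, innermost to outermost.  Closely spaced double LAGs are carried
#' as flagged adjacent pairs and collapsed to one annual mark by
#' \code{\link{collapse_double_lags}}.
#'
#' @param turtle_id Turtle identifier.
#' @param lag_diameters Ordered LAG diameters (mm), innermost first.
#' @param double_flags Logical per LAG: member of a closely spaced double.
#' @param section_diameter Humerus cross-section diameter \eqn{D_{final}}
#'   (mm).
#' @param resorption_diameter Diameter of the resorption core (mm); LAGs
#'   below this diameter have been destroyed by remodelling.
#' @param otc_diameter Optional diameter of the fluorescent OTC mark (mm).
#' @return An object of class \code{bone_profile}.
#' @export
bone_profile <- function(turtle_id, lag_diameters,
                         double_flags = rep(FALSE, length(lag_diameters)),
                         section_diameter,
                         resorption_diameter = 0,
                         otc_diameter = NA_real_) {
  structure(
    list(turtle_id = as.character(turtle_id),
         lag_diameters = as.numeric(lag_diameters),
         double_flags = as.logical(double_flags),
         section_diameter = as.numeric(section_diameter),
         resorption_diameter = as.numeric(resorption_diameter),
         otc_diameter = as.numeric(otc_diameter)),
    class = "bone_profile")
}

#' Check a turtle record and bone profile against the type invariants
#'
#' Diagnostic only: returns one human-readable issue per violated
#' invariant, or a zero-length character vector when everything holds.
#' Negative observed somatic growth (recovery SCL below tagging SCL) is
#' permitted -- it occurs in real strandings -- so it is not flagged.
#'
#' @param record A \code{\link{turtle_record}}, or \code{NULL}.
#' @param profile A \code{\link{bone_profile}}, or \code{NULL}.
#' @return Character vector of issue descriptions (empty when valid).
#' @export
validate_record <- function(record = NULL, profile = NULL) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  if (!is.null(record)) {
    stopifnot(inherits(record, "turtle_record"))
    if (is.na(record$date_tagged) || is.na(record$date_stranded))
      add(sprintf("%s: missing tagging or stranding date", record$id))
    else if (record$date_tagged > record$date_stranded)
      add(sprintf("%s: date_tagged (%s) is after date_stranded (%s)",
                  record$id, record$date_tagged, record$date_stranded))
    if (!is.na(record$scl_at_tagging) && record$scl_at_tagging <= 0)
      add(sprintf("%s: scl_at_tagging must be > 0", record$id))
    if (!is.na(record$scl_at_recovery) && record$scl_at_recovery <= 0)
      add(sprintf("%s: scl_at_recovery must be > 0", record$id))
    if (!is.null(record$date_otc) && !is.na(record$date_tagged) &&
        !is.na(record$date_stranded) &&
        (record$date_otc < record$date_tagged ||
         record$date_otc > record$date_stranded))
      add(sprintf("%s: date_otc (%s) outside [date_tagged, date_stranded]",
                  record$id, record$date_otc))
  }

  if (!is.null(profile)) {
    stopifnot(inherits(profile, "bone_profile"))
    id <- profile$turtle_id
    collapsed <- tryCatch(
      collapse_double_lags(profile$lag_diameters, profile$double_flags),
      error = function(e) {
        add(sprintf("%s: malformed double-LAG flags (%s)", id,
                    conditionMessage(e)))
        NULL
      })
    if (!is.null(collapsed) && length(collapsed) > 1 &&
        any(diff(collapsed) <= 0))
      add(sprintf("%s: LAG diameters not strictly increasing after collapsing",
                  id))
    if (any(profile$lag_diameters <= profile$resorption_diameter))
      add(sprintf("%s: LAG diameter at or below the resorption core (%g mm)",
                  id, profile$resorption_diameter))
    if (any(profile$lag_diameters >= profile$section_diameter))
      add(sprintf("%s: LAG diameter at or above the section diameter D_final = %g mm",
                  id, profile$section_diameter))
    if (!is.na(profile$otc_diameter) &&
        profile$otc_diameter >= profile$section_diameter)
      add(sprintf("%s: OTC diameter at or above the section diameter D_final = %g mm",
                  id))
  }

  if (!is.null(record) && !is.null(profile) &&
      record$id != profile$turtle_id)
    add(sprintf("record id %s does not match bone profile id %s",
                record$id, profile$turtle_id))
  issues
}

#' @export
print.turtle_record <- function(x, ...) {
  cat(sprintf("Turtle %s: tagged %s at %.1f cm SCL; stranded %s at %.1f cm%s%s\n",
              x$id, x$date_tagged, x$scl_at_tagging, x$date_stranded,
              x$scl_at_recovery,
              if (!is.null(x$date_otc))
                sprintf("; OTC injected %s", x$date_otc) else "",
              if (x$fibropapilloma) "; fibropapilloma present" else ""))
  invisible(x)
}

#' @export
print.bone_profile <- function(x, ...) {
  cat(sprintf("Humerus profile %s: %d LAG(s), section %.2f mm, resorption core %.2f mm%s\n",
              x$turtle_id, length(x$lag_diameters), x$section_diameter,
              x$resorption_diameter,
              if (!is.na(x$otc_diameter))
                sprintf(", OTC mark %.2f mm", x$otc_diameter) else ""))
  invisible(x)
}
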