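#' Run the skeletochronology validation pipeline
#'
#' End-to-end analysis of a set of turtle records and humerus profiles:
#' collapses double LAGs, assigns calendar years, selects the LAG
#' deposited closest to each tagging date (falling back to the OTC mark
#' when the tagging-era LAG lies inside the resorption core),
#' back-calculates SCL at tagging via the BPH equation, compares the
#' estimates against the SCLs measured at tagging (paired differences,
#' exact Wilcoxon signed-rank test, mean absolute difference, column
#' summaries), and infers the seasonal LAG deposition window from the OTC
#' timing comparisons.
#'
#' @param turtles Data frame in the \code{turtles.csv} schema: \code{id},
#'   \code{date_tagged}, \code{scl_tagging_cm}, \code{date_otc},
#'   \code{date_stranded}, \code{scl_recovery_cm}, \code{fibropapilloma}.
#' @param bones Data frame in the \code{bones.csv} schema:
#'   \code{turtle_id}, \code{lag_index}, \code{lag_diameter_mm},
#'   \code{is_double}, \code{section_diameter_mm},
#'   \code{resorption_diameter_mm}, \code{otc_diameter_mm}.
#' @param params A \code{\link{bph_params}} object.
#' @param season A \code{\link{deposition_season}} object.
#' @param tolerance_cm Coincidence tolerance for the OTC timing
#'   classification (cm).
#' @return An object of class \code{skelchron}; see
#'   \code{\link{print.skelchron}}, \code{\link{summary.skelchron}},
#'   \code{\link{residuals.skelchron}}.
#' @examples
#' fix <- hawaii_greens()
#' fit <- skelchron(fix$turtles, fix$bones)
#' fit
#' residuals(fit)
#' @export
skelchron <- function(turtles, bones, params = bph_params(),
                      season = deposition_season(), tolerance_cm = 0.1) {
  stopifnot(is.data.frame(turtles), is.data.frame(bones))
  turtles$date_tagged <- as.Date(turtles$date_tagged)
  turtles$date_stranded <- as.Date(turtles$date_stranded)
  turtles$date_otc <- as.Date(turtles$date_otc)

  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  comp <- list(); timing <- list(); growth <- list()
  for (i in seq_len(nrow(turtles))) {
    tr <- turtles[i, ]
    rec <- turtle_record(tr$id, tr$date_tagged, tr$scl_tagging_cm,
                         tr$date_stranded, tr$scl_recovery_cm,
                         date_otc = tr$date_otc,
                         fibropapilloma = isTRUE(tr$fibropapilloma))
    b <- bones[bones$turtle_id == tr$id, , drop = FALSE]
    if (nrow(b) == 0) {
      note("%s: no bone profile; skipped", tr$id)
      next
    }
    b <- b[order(b$lag_index), , drop = FALSE]
    prof <- bone_profile(tr$id, b$lag_diameter_mm, b$is_double,
                         section_diameter = b$section_diameter_mm[1],
                         resorption_diameter = b$resorption_diameter_mm[1],
                         otc_diameter = b$otc_diameter_mm[1])
    issues <- validate_record(rec, prof)
    if (length(issues)) {
      note("%s: validation failed (%s); skipped", tr$id,
           paste(issues, collapse = "; "))
      next
    }

    collapsed <- collapse_double_lags(prof$lag_diameters, prof$double_flags)
    edge_mm <- prof$section_diameter - max(collapsed)
    edge_growth <- edge_mm > season$edge_growth_threshold_mm
    assignments <- assign_lag_years(length(collapsed), rec$date_stranded,
                                    edge_growth, season)
    note("%s: %d annual LAG(s); outermost year %d (%s; edge growth %.3f mm)",
         tr$id, length(collapsed), max(assignments$calendar_year),
         assignments$basis[nrow(assignments)], edge_mm)

    growth[[tr$id]] <- growth_history(prof, assignments$calendar_year, rec,
                                      params)

    sel <- select_lag_nearest_date(assignments, rec$date_tagged, season)
    if (sel$use_otc_fallback) {
      if (!is.na(prof$otc_diameter)) {
        est <- otc_fallback_length(prof, rec, params)
        lag_year <- sel$ideal_year
        basis <- "otc_fallback"
        note("%s: tagging-era LAG (%d) inside resorption core; SCL from OTC mark",
             tr$id, sel$ideal_year)
      } else {
        note("%s: tagging-era LAG resorbed and no OTC mark; excluded from validation",
             tr$id)
        next
      }
    } else {
      est <- back_calculate_length(collapsed[sel$lag_index],
                                   prof$section_diameter,
                                   rec$scl_at_recovery, params)
      lag_year <- sel$calendar_year
      basis <- "lag"
      note("%s: LAG nearest tagging (%s) is year %d", tr$id,
           rec$date_tagged, lag_year)
    }
    comp[[tr$id]] <- data.frame(
      id = tr$id, date_stranded = rec$date_stranded,
      scl_stranding = rec$scl_at_recovery, date_tagged = rec$date_tagged,
      scl_tagging = rec$scl_at_tagging, estimated_scl = est,
      lag_year = lag_year, basis = basis, stringsAsFactors = FALSE)

    # OTC timing comparison: requires a measurable OTC mark and a
    # retained calendar-matched LAG
    if (!is.na(prof$otc_diameter) && !is.null(rec$date_otc)) {
      scl_otc <- otc_fallback_length(prof, rec, params)
      m <- select_lag_nearest_date(assignments, rec$date_otc, season)
      if (!m$use_otc_fallback) {
        scl_lag <- back_calculate_length(collapsed[m$lag_index],
                                         prof$section_diameter,
                                         rec$scl_at_recovery, params)
        scl_meas <- if (rec$date_otc == rec$date_tagged)
          rec$scl_at_tagging else NA_real_
        timing[[tr$id]] <- data.frame(
          turtle_id = tr$id, injection_date = rec$date_otc,
          scl_measured = scl_meas, scl_from_otc = scl_otc,
          scl_from_lag = scl_lag, lag_year = m$calendar_year,
          otc_difference = round_half_away(scl_meas - scl_otc, 1),
          relation = classify_deposition(scl_otc, scl_lag, tolerance_cm),
          stringsAsFactors = FALSE)
      } else {
        note("%s: calendar-matched LAG for the OTC date is resorbed; excluded from timing",
             tr$id)
      }
    }
  }

  comparison <- do.call(rbind, unname(comp))
  if (is.null(comparison) || nrow(comparison) == 0)
    stop("no turtle passed validation and selection; nothing to analyse")
  diffs <- paired_differences(comparison$scl_tagging,
                              comparison$estimated_scl, comparison$id)
  wx <- tryCatch(wilcoxon_signed_rank(diffs), error = function(e) {
    note("Wilcoxon test degenerate: %s", conditionMessage(e))
    NULL
  })
  fallback_ids <- comparison$id[comparison$basis == "otc_fallback"]
  mad_all <- mean_absolute_difference(diffs)
  mad_excl <- if (length(fallback_ids) &&
                  length(fallback_ids) < nrow(comparison))
    mean_absolute_difference(diffs, exclude_ids = fallback_ids)
    else NA_real_
  summarise <- function(v) tryCatch(column_summary(v),
                                    error = function(e) NULL)

  timing_df <- do.call(rbind, unname(timing))
  window <- NULL; timing_mad <- NA_real_; timing_se <- NA_real_
  if (!is.null(timing_df) && nrow(timing_df) > 0) {
    window <- infer_deposition_window(timing_df)
    od <- timing_df$otc_difference[!is.na(timing_df$otc_difference)]
    if (length(od)) timing_mad <- mean(abs(od))
    if (length(od) >= 2) timing_se <- standard_error(od)
  }

  structure(list(
    comparison = comparison, diffs = diffs, wilcoxon = wx,
    mean_abs_difference = mad_all,
    mean_abs_difference_excl_fallback = mad_excl,
    measured_summary = summarise(comparison$scl_tagging),
    estimated_summary = summarise(comparison$estimated_scl),
    timing = timing_df, window = window,
    timing_mean_abs_difference = timing_mad, timing_se = timing_se,
    growth = growth, params = params, season = season,
    tolerance_cm = tolerance_cm, log = log),
    class = "skelchron")
}

fmt_summary <- function(s) {
  if (is.null(s)) return("n/a")
  sprintf("%.1f-%.1f cm (mean +/- SD = %.1f +/- %.1f)",
          s$min, s$max, s$mean, s$sd)
}

#' @describeIn skelchron Comparison-table view of the fitted pipeline.
#' @param x,object A \code{skelchron} object.
#' @param ... Unused.
#' @export
print.skelchron <- function(x, ...) {
  cat(sprintf("Skeletochronological back-calculation validation (%d turtles)\n\n",
              nrow(x$comparison)))
  tab <- data.frame(
    ID = x$comparison$id,
    Stranded = format(x$comparison$date_stranded, "%d-%m-%y"),
    `SCL.strand` = sprintf("%.1f", x$comparison$scl_stranding),
    Tagged = format(x$comparison$date_tagged, "%d-%m-%y"),
    `SCL.tag` = sprintf("%.1f", x$comparison$scl_tagging),
    `SCL.est` = sprintf("%.1f%s", x$comparison$estimated_scl,
                        ifelse(x$comparison$basis == "otc_fallback", "*", "")),
    Year = x$comparison$lag_year,
    Diff = sprintf("%.1f", x$diffs$difference),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(tab, row.names = FALSE)
  if (any(x$comparison$basis == "otc_fallback"))
    cat("  * SCL back-calculated from the OTC-mark diameter (tagging-era LAG resorbed)\n")
  cat(sprintf("\nMean absolute difference: %.1f cm", x$mean_abs_difference))
  if (!is.na(x$mean_abs_difference_excl_fallback))
    cat(sprintf(" (%.1f cm excluding OTC-fallback estimates)",
                x$mean_abs_difference_excl_fallback))
  cat("\n")
  if (!is.null(x$wilcoxon)) print(x$wilcoxon)
  cat(sprintf("Measured SCL at tagging:  %s\n", fmt_summary(x$measured_summary)))
  cat(sprintf("Estimated SCL at tagging: %s\n", fmt_summary(x$estimated_summary)))
  invisible(x)
}

#' @describeIn skelchron Adds the OTC timing table, deposition window and
#'   the per-turtle decision log.
#' @export
summary.skelchron <- function(object, ...) {
  print(object)
  if (!is.null(object$timing) && nrow(object$timing)) {
    cat("\nOTC timing comparison:\n")
    tt <- object$timing
    tt$injection_date <- format(tt$injection_date, "%d-%m-%y")
    tt$scl_from_otc <- round(tt$scl_from_otc, 1)
    tt$scl_from_lag <- round(tt$scl_from_lag, 1)
    print(tt[, c("turtle_id", "injection_date", "scl_from_otc",
                 "otc_difference", "scl_from_lag", "lag_year", "relation")],
          row.names = FALSE)
    if (!is.na(object$timing_mean_abs_difference))
      cat(sprintf("Mean absolute OTC-vs-measured difference: %.1f cm (SE %.1f cm)\n",
                  object$timing_mean_abs_difference, object$timing_se))
    if (!is.null(object$window)) print(object$window)
  }
  cat("\nPer-turtle decisions:\n")
  cat(paste0("  ", object$log, collapse = "\n"), "\n")
  invisible(object)
}

#' @describeIn skelchron Paired measured-minus-estimated SCL differences
#'   (cm), named by turtle id.
#' @export
residuals.skelchron <- function(object, ...) {
  stats::setNames(object$diffs$difference, object$diffs$id)
}

#' @describeIn skelchron The BPH back-calculation constants used.
#' @export
coef.skelchron <- function(object, ...) {
  unlist(object$params)
}

#' @describeIn skelchron Measured vs back-calculated SCL at tagging with
#'   the 1:1 line.
#' @export
plot.skelchron <- function(x, ...) {
  graphics::plot(x$comparison$scl_tagging, x$comparison$estimated_scl,
                 xlab = "SCL measured at tagging (cm)",
                 ylab = "Back-calculated SCL at tagging (cm)",
                 pch = ifelse(x$comparison$basis == "otc_fallback", 17, 19),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
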