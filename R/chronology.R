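#' Deposition-season configuration
#'
#' LAGs are deposited once per year in a spring window running from just
#' after December to mid-May.  The season is summarised by a nominal
#' deposition day-of-year (used as each LAG's nominal calendar date) and
#' the day-of-year by which deposition is complete.  "Little to no
#' differentiation" between the outermost LAG and the bone edge is
#' operationalised by a diameter threshold.
#'
#' @param nominal_doy Nominal deposition day-of-year (default 91, April 1,
#'   the midpoint of the after-December-to-mid-May window).
#' @param window_end_doy Day-of-year by which annual deposition is complete
#'   (default 135, May 15).
#' @param edge_growth_threshold_mm Edge growth (\eqn{D_{final}} minus the
#'   outermost LAG diameter) at or below which the outermost LAG is treated
#'   as undifferentiated from the bone edge (default 0.05 mm).
#' @return An object of class \code{deposition_season}.
#' @export
deposition_season <- function(nominal_doy = 91, window_end_doy = 135,
                              edge_growth_threshold_mm = 0.05) {
  stopifnot(nominal_doy >= 1, nominal_doy <= 366,
            window_end_doy >= nominal_doy, window_end_doy <= 366,
            edge_growth_threshold_mm >= 0)
  structure(list(nominal_doy = nominal_doy,
                 window_end_doy = window_end_doy,
                 edge_growth_threshold_mm = edge_growth_threshold_mm),
            class = "deposition_season")
}

day_of_year <- function(date) as.integer(format(as.Date(date), "%j"))

calendar_year <- function(date) as.integer(format(as.Date(date), "%Y"))

#' Nominal calendar date of the LAG deposited in a given year
#'
#' @param year Integer calendar year(s).
#' @param season A \code{\link{deposition_season}}.
#' @return A \code{Date} vector: January 1 of each year plus the nominal
#'   deposition day-of-year.
#' @export
nominal_deposition_date <- function(year, season = deposition_season()) {
  as.Date(sprintf("%d-01-01", as.integer(year))) + (season$nominal_doy - 1)
}

#' Collapse closely spaced double LAGs to single annual marks
#'
#' A double LAG is a pair of adjacent, closely spaced lines deposited
#' within one annual cycle; it is read as a single annual mark whose
#' diameter is the outer (larger) line of the pair.  Flags mark both
#' members of each pair; doubles in consecutive years form even-length
#' flagged runs, read as consecutive pairs.  An odd-length flagged run
#' (an unpaired line) is a structural error.
#'
#' @param diameters Ordered LAG diameters (mm), innermost first, strictly
#'   increasing.
#' @param double_flags Logical vector, same length; \code{TRUE} for both
#'   members of each double pair.
#' @return Collapsed, strictly increasing diameter vector (one entry per
#'   annual mark).
#' @export
collapse_double_lags <- function(diameters,
                                 double_flags = rep(FALSE, length(diameters))) {
  n <- length(diameters)
  if (length(double_flags) != n)
    stop("double_flags must align 1:1 with diameters")
  if (n == 0) return(numeric(0))
  if (!any(double_flags)) return(as.numeric(diameters))
  r <- rle(as.logical(double_flags))
  if (any(r$values & r$lengths %% 2L != 0L))
    stop("double-LAG flags must mark adjacent pairs (even-length runs)")
  starts <- cumsum(r$lengths) - r$lengths + 1L
  keep <- rep(TRUE, n)
  # drop the inner (first) member of each flagged pair
  for (j in which(r$values))
    keep[seq(starts[j], by = 2L, length.out = r$lengths[j] / 2L)] <- FALSE
  out <- as.numeric(diameters[keep])
  if (length(out) > 1 && any(diff(out) <= 0))
    stop("collapsed LAG diameters are not strictly increasing")
  out
}

#' Assign calendar years to collapsed LAGs
#'
#' The most recent year is assigned to the LAG closest to the outer
#' circumference; years then count back by one per LAG inward.  For the
#' outermost LAG the year depends on where the stranding date falls in the
#' annual deposition cycle: after the deposition window has closed the
#' current year's LAG is present; within the window it is present only
#' when there is little to no differentiation between the final LAG and
#' the bone edge (no measurable edge growth); before the nominal
#' deposition date the outermost LAG belongs to the previous year.
#'
#' @param n_lags Number of collapsed LAGs (>= 1).
#' @param date_stranded Stranding date.
#' @param edge_growth_present Logical: measurable bone growth beyond the
#'   outermost LAG (edge growth above the season's threshold).
#' @param season A \code{\link{deposition_season}}.
#' @return Data frame with one row per LAG (innermost first):
#'   \code{lag_index}, \code{calendar_year}, and \code{basis}, one of
#'   \code{"edge_same_year"}, \code{"edge_previous_year"},
#'   \code{"counted_back"}.
#' @export
assign_lag_years <- function(n_lags, date_stranded, edge_growth_present,
                             season = deposition_season()) {
  if (!is.numeric(n_lags) || n_lags < 1)
    stop("empty profile: at least one LAG is required")
  n_lags <- as.integer(n_lags)
  date_stranded <- as.Date(date_stranded)
  doy <- day_of_year(date_stranded)
  yr <- calendar_year(date_stranded)
  deposited_this_year <-
    doy > season$window_end_doy ||
    (doy >= season$nominal_doy && !isTRUE(edge_growth_present))
  outer_year <- if (deposited_this_year) yr else yr - 1L
  basis_outer <- if (deposited_this_year) "edge_same_year"
                 else "edge_previous_year"
  years <- seq.int(outer_year - n_lags + 1L, outer_year)
  data.frame(
    lag_index = seq_len(n_lags),
    calendar_year = years,
    basis = c(rep("counted_back", n_lags - 1L), basis_outer),
    stringsAsFactors = FALSE)
}

#' Select the LAG deposited closest to a target date
#'
#' Each LAG's nominal deposition date is the season's nominal day-of-year
#' in its assigned calendar year; the LAG minimising absolute day distance
#' to the target date is selected, ties broken toward the later LAG.  When
#' the nearest plausible deposition year precedes the earliest retained
#' LAG (the tagging-era LAG lies inside the resorption core), a fallback
#' signal is returned instructing the caller to use the OTC mark instead.
#'
#' @param assignments Data frame from \code{\link{assign_lag_years}}.
#' @param target_date Date to match (e.g. the tagging or OTC injection
#'   date).
#' @param season A \code{\link{deposition_season}}.
#' @return List of class \code{lag_selection}: \code{lag_index} and
#'   \code{calendar_year} of the selected LAG (\code{NA} when resorbed),
#'   \code{ideal_year} (the year whose nominal deposition date is nearest
#'   the target), and \code{use_otc_fallback} (logical).
#' @export
select_lag_nearest_date <- function(assignments, target_date,
                                    season = deposition_season()) {
  target_date <- as.Date(target_date)
  ty <- calendar_year(target_date)
  cand <- (ty - 1L):(ty + 1L)
  dist_cand <- abs(as.numeric(nominal_deposition_date(cand, season) -
                              target_date))
  # tie toward the later year
  ideal_year <- cand[max(which(dist_cand == min(dist_cand)))]

  if (is.null(assignments) || nrow(assignments) == 0 ||
      ideal_year < min(assignments$calendar_year)) {
    return(structure(list(lag_index = NA_integer_,
                          calendar_year = NA_integer_,
                          ideal_year = ideal_year,
                          use_otc_fallback = TRUE),
                     class = "lag_selection"))
  }
  dist <- abs(as.numeric(
    nominal_deposition_date(assignments$calendar_year, season) - target_date))
  i <- max(which(dist == min(dist)))  # tie toward the later LAG
  structure(list(lag_index = assignments$lag_index[i],
                 calendar_year = assignments$calendar_year[i],
                 ideal_year = ideal_year,
                 use_otc_fallback = FALSE),
            class = "lag_selection")
}
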