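# round half away from zero (Table-style rounding; base round() is banker's)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

#' Paired measured-minus-estimated SCL differences
#'
#' Element-wise \code{measured - estimated}, rounded half-away-from-zero
#' to 0.1 cm (the SCL reporting resolution) before any statistic is
#' computed, as in the published comparison tables.
#'
#' @param measured SCLs measured in the field (cm).
#' @param estimated Back-calculated SCLs (cm), same length.
#' @param ids Optional identifiers, same length.
#' @return An object of class \code{paired_diffs}: data frame with columns
#'   \code{id}, \code{measured}, \code{estimated}, \code{difference}.
#' @examples
#' paired_differences(c(55.1, 83.8), c(55.1, 84.6), c("CM-1", "CM-10"))
#' @export
paired_differences <- function(measured, estimated, ids = NULL) {
  if (length(measured) != length(estimated))
    stop("measured and estimated must have equal length")
  if (length(measured) < 1) stop("at least one pair is required")
  if (is.null(ids)) ids <- as.character(seq_along(measured))
  out <- data.frame(id = as.character(ids),
                    measured = as.numeric(measured),
                    estimated = as.numeric(estimated),
                    difference = round_half_away(measured - estimated, 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_diffs", "data.frame")
  out
}

diff_values <- function(diffs) {
  if (inherits(diffs, "paired_diffs")) diffs$difference else as.numeric(diffs)
}

# exact null distribution of the positive-rank sum over all 2^N sign
# assignments, computed by convolution over the (doubled) midrank vector;
# returns probabilities on the grid 0, 0.5, 1, ... sum(ranks)
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  counts <- c(1, rep(0, sum(r2)))
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks)
}

#' Exact Wilcoxon signed-rank test on paired SCL differences
#'
#' The paired-sample Wilcoxon test as classically tabulated: zero
#' differences are dropped (so \code{n} is the count of nonzero pairs),
#' absolute differences are ranked with midranks for ties, and the
#' statistic is \eqn{T = \min(T^+, T^-)}.  The two-sided p-value is exact,
#' from the null distribution over all \eqn{2^N} equiprobable sign
#' assignments of the observed midrank vector
#' (\eqn{p = P(T^+ \le T) + P(T^+ \ge N(N+1)/2 - T)}).  For \eqn{N > 25}
#' a normal approximation with tie-corrected variance and continuity
#' correction is used instead.
#'
#' @param diffs A \code{\link{paired_differences}} object or a numeric
#'   vector of differences.
#' @return List of class \code{wilcoxon_exact}: \code{statistic} (T),
#'   \code{n} (nonzero pairs), \code{p.value}, \code{T_plus},
#'   \code{T_minus}, \code{exact} (logical).
#' @examples
#' wilcoxon_signed_rank(c(0.0, -0.2, -0.4, 0.6, 0.4, -0.8, 0.0, -0.3, -1.5, 0.0))
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diff_values(diffs)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate sample: all differences are zero")
  ranks <- rank(abs(d))
  t_plus <- sum(ranks[d > 0])
  t_minus <- sum(ranks[d < 0])
  t_obs <- min(t_plus, t_minus)
  total <- n * (n + 1) / 2
  exact <- n <= 25
  if (exact) {
    probs <- signed_rank_null(ranks)
    grid <- seq(0, total, by = 0.5)
    p <- sum(probs[grid <= t_obs + 1e-9]) +
         sum(probs[grid >= total - t_obs - 1e-9])
    p <- min(1, p)
  } else {
    ties <- table(ranks)
    mu <- total / 2
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (t_plus - mu - sign(t_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = t_obs, n = n, p.value = p,
                 T_plus = t_plus, T_minus = t_minus, exact = exact),
            class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank test (%s): T = %g, N = %d, two-sided p = %.4g\n",
              if (x$exact) "exact" else "normal approximation",
              x$statistic, x$n, x$p.value))
  invisible(x)
}

#' Mean absolute paired difference
#'
#' @param diffs A \code{\link{paired_differences}} object or numeric
#'   vector.
#' @param exclude_ids Optional ids to drop before averaging (e.g. turtles
#'   whose estimate came from the OTC-mark fallback).
#' @return Mean of \code{|difference|} (cm), at full precision; round to
#'   0.1 cm for reporting.
#' @export
mean_absolute_difference <- function(diffs, exclude_ids = NULL) {
  if (!is.null(exclude_ids)) {
    if (!inherits(diffs, "paired_diffs"))
      stop("exclude_ids requires a paired_differences object")
    diffs <- diffs[!(diffs$id %in% exclude_ids), , drop = FALSE]
  }
  d <- diff_values(diffs)
  d <- d[!is.na(d)]
  if (length(d) == 0)
    stop("degenerate sample: no differences left after exclusions")
  mean(abs(d))
}

#' Standard error of absolute differences
#'
#' Sample standard deviation (n - 1 denominator) of the absolute values,
#' divided by the square root of the sample size.
#'
#' @param values Numeric vector (cm), length >= 2.
#' @return Standard error (cm).
#' @export
standard_error <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("degenerate sample: standard error needs at least 2 values")
  stats::sd(abs(values)) / sqrt(length(values))
}

#' Mean, SD and range of a measurement column
#'
#' @param values Numeric vector (cm), length >= 2.
#' @return List with \code{mean}, \code{sd} (n - 1 denominator),
#'   \code{min}, \code{max}.
#' @export
column_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("degenerate sample: summary needs at least 2 values")
  list(mean = mean(values), sd = stats::sd(values),
       min = min(values), max = max(values))
}
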