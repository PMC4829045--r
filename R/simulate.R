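#' Configuration for the bone-growth simulator
#'
#' Parameters of the forward simulator in \code{\link{simulate_population}}.
#' Bone growth follows a monotone von Bertalanffy trajectory on the
#' humerus-diameter axis and somatic size is mapped through the BPH
#' allometry with an individual lognormal proportionality factor, so the
#' back-calculation assumptions hold by construction.  Defaults emulate
#' the Hawaiian green turtle study conditions: ten turtles spanning
#' roughly 44--86 cm SCL, one spring-deposited LAG per year (day-of-year
#' 91 +/- 10), occasional closely spaced double LAGs, a resorption core
#' advancing with age, 0.5--9.5 years at large between tagging and
#' stranding, and small measurement errors on lengths and diameters.
#'
#' @param n_turtles Number of turtles.
#' @param linf_mean_cm,linf_sd_cm Mean and SD of asymptotic SCL across
#'   individuals (cm).
#' @param growth_k von Bertalanffy rate constant (per year) of the bone
#'   trajectory.
#' @param hatch_date_range Date range from which hatch dates are drawn.
#' @param individual_proportionality_sd Lognormal SD of the individual
#'   BPH proportionality factor (dimensionless).
#' @param deposition_doy_mean,deposition_doy_sd Mean and SD of the LAG
#'   deposition day-of-year.
#' @param p_double_lag Probability a LAG is emitted as a closely spaced
#'   double pair.
#' @param double_gap_range_mm Range of the inner-line offset of a double
#'   pair (mm).
#' @param resorption_rate_mm_yr Advance of the resorption front (mm of
#'   diameter per year of age); LAGs below the front are destroyed.
#' @param scl_error_sd SD of SCL measurement error (cm).
#' @param diameter_error_sd SD of diameter measurement error (mm).
#' @param otc_fraction Probability a turtle receives one OTC injection.
#' @param otc_uniform_doy If \code{TRUE}, injections are spread uniformly
#'   over the year after tagging; if \code{FALSE} (default) injection
#'   happens at tagging, as in the field studies.
#' @param years_at_large_range Range of time at large between tagging and
#'   stranding (years).
#' @param stranding_date_range Date range from which stranding dates are
#'   drawn.
#' @param stranding_doy_range Optional day-of-year range (length 2) to
#'   which stranding dates are restricted, e.g. \code{c(182, 350)} for
#'   strandings after the deposition season, where season-based year
#'   assignment is determinate.  \code{NULL} (default) leaves strandings
#'   uniform over the date range.
#' @param tag_at_deposition If \code{TRUE} (default) tagging coincides
#'   with a LAG deposition event (spring field season), which makes the
#'   noise-free pipeline exactly unbiased.
#' @param params A \code{\link{bph_params}} object.
#' @param seed Integer seed governing all draws.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_turtles = 10,
                       linf_mean_cm = 95, linf_sd_cm = 8,
                       growth_k = 0.08,
                       hatch_date_range = as.Date(c("1975-01-01",
                                                    "1990-12-31")),
                       individual_proportionality_sd = 0.05,
                       deposition_doy_mean = 91, deposition_doy_sd = 10,
                       p_double_lag = 0.1,
                       double_gap_range_mm = c(0.05, 0.15),
                       resorption_rate_mm_yr = 0.35,
                       scl_error_sd = 0.2, diameter_error_sd = 0.05,
                       otc_fraction = 1, otc_uniform_doy = FALSE,
                       years_at_large_range = c(0.5, 9.5),
                       stranding_date_range = as.Date(c("1999-01-01",
                                                        "2004-12-31")),
                       stranding_doy_range = NULL,
                       tag_at_deposition = TRUE,
                       params = bph_params(),
                       seed = 1L) {
  cfg <- list(n_turtles = as.integer(n_turtles),
              linf_mean_cm = linf_mean_cm, linf_sd_cm = linf_sd_cm,
              growth_k = growth_k,
              hatch_date_range = as.Date(hatch_date_range),
              individual_proportionality_sd = individual_proportionality_sd,
              deposition_doy_mean = deposition_doy_mean,
              deposition_doy_sd = deposition_doy_sd,
              p_double_lag = p_double_lag,
              double_gap_range_mm = double_gap_range_mm,
              resorption_rate_mm_yr = resorption_rate_mm_yr,
              scl_error_sd = scl_error_sd,
              diameter_error_sd = diameter_error_sd,
              otc_fraction = otc_fraction,
              otc_uniform_doy = isTRUE(otc_uniform_doy),
              years_at_large_range = years_at_large_range,
              stranding_date_range = as.Date(stranding_date_range),
              stranding_doy_range = stranding_doy_range,
              tag_at_deposition = isTRUE(tag_at_deposition),
              params = params,
              seed = as.integer(seed))
  with(cfg, {
    if (n_turtles < 1) stop("n_turtles must be >= 1")
    if (growth_k <= 0) stop("growth_k must be > 0")
    if (individual_proportionality_sd < 0 || deposition_doy_sd < 0 ||
        scl_error_sd < 0 || diameter_error_sd < 0 ||
        resorption_rate_mm_yr < 0)
      stop("rates and standard deviations must be >= 0")
    if (p_double_lag < 0 || p_double_lag > 1 ||
        otc_fraction < 0 || otc_fraction > 1)
      stop("probabilities must lie in [0, 1]")
    if (deposition_doy_mean < 1 || deposition_doy_mean > 366)
      stop("deposition_doy_mean must lie in [1, 366]")
  })
  structure(cfg, class = "sim_config")
}

# diameter and (true) SCL of turtle with parameters th at age t (years)
sim_diameter_at <- function(t, th, params) {
  params$d_op + (th$dinf - params$d_op) * (1 - exp(-th$k * t))
}
sim_scl_at <- function(t, th, params) {
  th$s * bph_allometry(sim_diameter_at(t, th, params), params)
}

#' Simulate a tagged, OTC-injected turtle population with bone profiles
#'
#' Forward-simulates individual somatic and bone growth, annual spring LAG
#' deposition with individual variability, double LAGs, resorption of
#' early LAGs, an OTC injection time-stamping the bone, and measurement
#' error, then emits turtle and bone tables in the standard CSV schemas
#' together with the complete ground truth.  Deterministic given
#' \code{config$seed}; per-turtle substreams keep individual turtles
#' reproducible when \code{n_turtles} changes.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{turtles} and \code{bones} (data frames in the
#'   \code{\link{read_turtle_tables}} schemas) and \code{truth}, a list
#'   with one entry per turtle: individual parameters (\code{s},
#'   \code{linf}, \code{dinf}, \code{k}, \code{hatch_date}), the
#'   \code{lags} data frame (every deposited LAG: year, date, true
#'   diameter and SCL, resorbed flag), and true sizes/diameters at
#'   tagging, OTC injection and stranding.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  params <- cfg$params
  set.seed(cfg$seed)
  substreams <- sample.int(.Machine$integer.max - 1L, cfg$n_turtles)

  turtles <- list(); bones <- list(); truth <- list()
  for (i in seq_len(cfg$n_turtles)) {
    set.seed(substreams[i])
    id <- sprintf("SIM-%03d", i)
    s <- exp(stats::rnorm(1, 0, cfg$individual_proportionality_sd))
    linf <- max(70, stats::rnorm(1, cfg$linf_mean_cm, cfg$linf_sd_cm))
    dinf <- params$d_op + ((linf / s - params$l_op) / params$b)^(1 / params$c)
    th <- list(s = s, linf = linf, dinf = dinf, k = cfg$growth_k)

    hatch <- cfg$hatch_date_range[1] +
      floor(stats::runif(1) *
            (as.numeric(diff(cfg$hatch_date_range)) + 1))
    strand <- cfg$stranding_date_range[1] +
      floor(stats::runif(1) *
            (as.numeric(diff(cfg$stranding_date_range)) + 1))
    if (!is.null(cfg$stranding_doy_range)) {
      doy_s <- round(stats::runif(1, cfg$stranding_doy_range[1],
                                  cfg$stranding_doy_range[2]))
      strand <- as.Date(sprintf("%d-01-01", calendar_year(strand))) +
        (doy_s - 1)
    }
    strand <- max(strand, hatch + round(6 * 365.25))

    # one deposition event per calendar year between hatch and stranding
    yrs <- (calendar_year(hatch) + 1L):calendar_year(strand)
    doy <- round(stats::rnorm(length(yrs), cfg$deposition_doy_mean,
                              cfg$deposition_doy_sd))
    doy <- pmin(pmax(doy, 1), 365)
    dep_dates <- as.Date(sprintf("%d-01-01", yrs)) + (doy - 1)
    keep <- dep_dates > hatch & dep_dates < strand
    yrs <- yrs[keep]; dep_dates <- dep_dates[keep]
    if (length(yrs) < 2) next  # too young to carry a usable record
    age_at <- function(d) as.numeric(d - hatch) / 365.25
    d_true <- sim_diameter_at(age_at(dep_dates), th, params)
    l_true <- th$s * bph_allometry(d_true, params)

    # tagging at the deposition event nearest the target time at large
    yal <- stats::runif(1, cfg$years_at_large_range[1],
                        cfg$years_at_large_range[2])
    target_tag <- strand - round(yal * 365.25)
    j_tag <- which.min(abs(as.numeric(dep_dates - target_tag)))
    tag_date <- if (cfg$tag_at_deposition) dep_dates[j_tag]
                else max(hatch + 1, target_tag)
    scl_tag_true <- sim_scl_at(age_at(tag_date), th, params)

    has_otc <- stats::runif(1) < cfg$otc_fraction
    otc_date <- as.Date(NA)
    d_otc <- NA_real_; scl_otc_true <- NA_real_
    if (has_otc) {
      otc_date <- if (cfg$otc_uniform_doy)
        min(strand - 1, tag_date + floor(stats::runif(1, 0, 365)))
        else tag_date
      d_otc <- sim_diameter_at(age_at(otc_date), th, params)
      scl_otc_true <- th$s * bph_allometry(d_otc, params)
    }

    age_strand <- age_at(strand)
    d_final_true <- sim_diameter_at(age_strand, th, params)
    l_final_true <- th$s * bph_allometry(d_final_true, params)

    front <- cfg$resorption_rate_mm_yr * age_strand
    resorbed <- d_true < front

    lag_truth <- data.frame(year = yrs, date = dep_dates,
                            diameter_mm = d_true, scl_cm = l_true,
                            resorbed = resorbed)
    retained <- which(!resorbed)
    if (length(retained) < 1) next

    # observed diameters: measurement error, redrawn until the profile
    # stays strictly increasing below the observed section diameter
    d_final_obs <- d_final_true +
      stats::rnorm(1, 0, cfg$diameter_error_sd)
    d_final_obs <- max(d_final_obs, max(d_true[retained]) + 1e-3)
    d_obs <- NULL
    for (try in 1:200) {
      cand <- d_true[retained] +
        stats::rnorm(length(retained), 0, cfg$diameter_error_sd)
      ok <- all(cand > front) && all(cand < d_final_obs) &&
        (length(cand) < 2 || all(diff(cand) > 0))
      if (ok) { d_obs <- cand; break }
    }
    if (is.null(d_obs)) d_obs <- d_true[retained]  # noise-dominated bone

    dbl <- stats::runif(length(retained)) < cfg$p_double_lag
    gaps <- stats::runif(length(retained), cfg$double_gap_range_mm[1],
                         cfg$double_gap_range_mm[2])
    diam_rows <- list()
    for (j in seq_along(retained)) {
      if (dbl[j]) {
        inner <- d_obs[j] - gaps[j]
        lower <- if (j > 1) d_obs[j - 1] else front
        inner <- max(inner, (lower + d_obs[j]) / 2)
        diam_rows[[j]] <- data.frame(d = c(inner, d_obs[j]),
                                     is_double = c(TRUE, TRUE))
      } else {
        diam_rows[[j]] <- data.frame(d = d_obs[j], is_double = FALSE)
      }
    }
    diam <- do.call(rbind, diam_rows)

    turtles[[i]] <- data.frame(
      id = id, date_tagged = tag_date,
      scl_tagging_cm = scl_tag_true +
        stats::rnorm(1, 0, cfg$scl_error_sd),
      date_otc = otc_date, date_stranded = strand,
      scl_recovery_cm = l_final_true +
        stats::rnorm(1, 0, cfg$scl_error_sd),
      fibropapilloma = stats::runif(1) < 0.6,
      stringsAsFactors = FALSE)
    bones[[i]] <- data.frame(
      turtle_id = id, lag_index = seq_len(nrow(diam)),
      lag_diameter_mm = diam$d, is_double = diam$is_double,
      section_diameter_mm = d_final_obs,
      resorption_diameter_mm = front,
      otc_diameter_mm = d_otc,  # OTC marks are read exactly under UV
      stringsAsFactors = FALSE)
    truth[[id]] <- list(
      s = s, linf = linf, dinf = dinf, k = cfg$growth_k,
      hatch_date = hatch, lags = lag_truth,
      tag_date = tag_date, tag_year = yrs[j_tag],
      scl_at_tagging = scl_tag_true,
      diameter_at_tagging = sim_diameter_at(age_at(tag_date), th, params),
      otc_date = otc_date, scl_at_otc = scl_otc_true,
      diameter_at_otc = d_otc,
      strand_date = strand, scl_at_stranding = l_final_true,
      diameter_at_stranding = d_final_true)
  }
  list(turtles = do.call(rbind, turtles),
       bones = do.call(rbind, bones),
       truth = truth)
}
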