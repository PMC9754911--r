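#' Configuration for the paired-schedule simulator
#'
#' Collects every generative parameter of the dual-forager simulator: fixed
#' effects on the square-root-hours scale, variance components, the breeding
#' phenology anchors, the nest-relief overlap lag, within-trip wet/dry bout
#' behaviour and the logger-rendering settings.
#'
#' All fixed effects (`beta_*`) act on the square root of trip duration in
#' hours, per 1 SD of the covariate: boldness scores are population-centred
#' (SD close to 1), ages are standardised internally against the colony age
#' distribution (mean 21.14, SD 7.67 years), date is standardised against the
#' season midpoint, and the coordination covariate is the partner's
#' previous-trip deviation on the sqrt-hours scale. The default stage
#' intercepts reproduce mean trip durations of about 5.6 days during
#' incubation and 2.7 days during chick-brooding.
#'
#' @param n_pairs Number of breeding pairs.
#' @param n_years Number of breeding seasons to spread pairs across.
#' @param seed Integer seed consumed by [simulate_study()]; `NULL` leaves the
#'   RNG state untouched.
#' @param beta Named list of fixed effects (sqrt-hours per SD). Recognised
#'   names: `intercept_incubation`, `intercept_brooding`, `sex_male`,
#'   `focal_boldness`, `partner_boldness`, `focal_age`, `focal_age_sq`,
#'   `partner_age`, `partner_age_sq`, `new_partner`, `date`, `coord`. Missing
#'   entries default to the values listed under Defaults.
#' @param sigma_pair_intercept,sigma_pair_slope,sigma_year,sigma_resid
#'   Standard deviations (sqrt-hours) of the pair random intercept, the pair
#'   random coordination slope, the year effect, and the trip-level residual.
#'   `sigma_resid` may be a single value or a named length-2 vector
#'   `c(incubation = , brooding = )`; the stage-specific defaults reproduce
#'   the observed stage spreads (5.6 +/- 4.3 d incubation, 2.7 +/- 1.4 d
#'   brooding on the raw scale) once pair and year variance are added.
#' @param rho_pair Correlation between pair intercept and pair slope.
#' @param overlap_lag_mean_h Mean of the exponential nest-relief lag (hours);
#'   the relieved bird departs this long after its partner's return. Default
#'   1.883 h (1 h 53 min).
#' @param season_start_md,mean_hatch_md,brooding_end_md Month-day strings
#'   (`"mm-dd"`) anchoring incubation start (default Dec 16), the mean hatch
#'   date (Mar 15 of the following calendar year) and the end of brooding
#'   (Apr 11).
#' @param hatch_sd_days SD (days) of the true hatch date around the mean.
#' @param min_trip_h Positive floor for generated trip durations (hours).
#' @param trip_wet_mean_h,trip_dry_mean_h Mean exponential bout lengths for
#'   on-water and flight bouts within a trip.
#' @param min_wet_bout_h Floor on wet-bout length (hours). Guarantees every
#'   on-water bout registers above the binned dialect's wet threshold, so the
#'   two dialects describe the same trip set by construction; sub-resolution
#'   spray contacts are below the wet threshold and are not modelled.
#' @param trip_dry_max_h Truncation for flight bouts; must stay below the 12-h
#'   dry spell that defines a return to land.
#' @param logger_dialect `"binned"` or `"state_change"`.
#' @param bin_width_min Bin width of the binned dialect (minutes).
#' @param wet_threshold_s Wet-seconds threshold above which a bin is wet.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_pairs = 4, seed = 1)
#' cfg$beta$coord
#' @export
sim_config <- function(n_pairs = 71,
                       n_years = 7,
                       seed = NULL,
                       beta = list(),
                       sigma_pair_intercept = 1.0,
                       sigma_pair_slope = 0.1,
                       sigma_year = 0.5,
                       sigma_resid = c(incubation = 4.3, brooding = 1.7),
                       rho_pair = 0,
                       overlap_lag_mean_h = 1.883,
                       season_start_md = "12-16",
                       mean_hatch_md = "03-15",
                       brooding_end_md = "04-11",
                       hatch_sd_days = 4,
                       min_trip_h = 2,
                       trip_wet_mean_h = 3,
                       trip_dry_mean_h = 2,
                       trip_dry_max_h = 11,
                       min_wet_bout_h = 0.2,
                       logger_dialect = c("binned", "state_change"),
                       bin_width_min = 10,
                       wet_threshold_s = 45) {
  beta_default <- list(
    intercept_incubation = 11.6,  # 11.6^2 = 134.56 h ~ 5.6 d
    intercept_brooding   = 8.05,  # 8.05^2 = 64.8 h  ~ 2.7 d
    sex_male = 0, focal_boldness = 0, partner_boldness = 0,
    focal_age = 0, focal_age_sq = 0, partner_age = 0, partner_age_sq = 0,
    new_partner = 0, date = 0, coord = 0.19
  )
  unknown <- setdiff(names(beta), names(beta_default))
  if (length(unknown) > 0) {
    stop("unknown beta term(s): ", paste(unknown, collapse = ", "))
  }
  beta_default[names(beta)] <- beta
  logger_dialect <- match.arg(logger_dialect)
  if (length(sigma_resid) == 1) {
    sigma_resid <- c(incubation = unname(sigma_resid),
                     brooding = unname(sigma_resid))
  }
  if (!all(c("incubation", "brooding") %in% names(sigma_resid))) {
    stop("sigma_resid must be a single value or named c(incubation=, brooding=)")
  }

  cfg <- list(
    n_pairs = n_pairs, n_years = n_years, seed = seed,
    beta = beta_default,
    sigma_pair_intercept = sigma_pair_intercept,
    sigma_pair_slope = sigma_pair_slope,
    sigma_year = sigma_year, sigma_resid = sigma_resid,
    rho_pair = rho_pair,
    overlap_lag_mean_h = overlap_lag_mean_h,
    season_start_md = season_start_md,
    mean_hatch_md = mean_hatch_md,
    brooding_end_md = brooding_end_md,
    hatch_sd_days = hatch_sd_days,
    min_trip_h = min_trip_h,
    trip_wet_mean_h = trip_wet_mean_h,
    trip_dry_mean_h = trip_dry_mean_h,
    trip_dry_max_h = trip_dry_max_h,
    min_wet_bout_h = min_wet_bout_h,
    logger_dialect = logger_dialect,
    bin_width_min = bin_width_min,
    wet_threshold_s = wet_threshold_s,
    # colony age distribution used to standardise ages inside the predictor
    age_mean = 21.14, age_sd = 7.67,
    # date standardisation: days since season start, centred mid-season
    date_center_d = 58, date_scale_d = 33.5
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sds <- c(cfg$sigma_pair_intercept, cfg$sigma_pair_slope, cfg$sigma_year,
           cfg$sigma_resid, cfg$hatch_sd_days)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (cfg$overlap_lag_mean_h < 0) stop("overlap_lag_mean_h must be >= 0")
  if (cfg$trip_dry_max_h >= 12) {
    stop("trip_dry_max_h must be < 12 h, or flight bouts would read as returns to land")
  }
  if (cfg$min_trip_h <= 0) stop("min_trip_h must be > 0")
  if (cfg$min_wet_bout_h < 0 || cfg$trip_wet_mean_h <= cfg$min_wet_bout_h) {
    stop("need 0 <= min_wet_bout_h < trip_wet_mean_h")
  }
  if (cfg$min_trip_h <= cfg$min_wet_bout_h) {
    stop("min_trip_h must exceed min_wet_bout_h")
  }
  if (abs(cfg$rho_pair) > 1) stop("rho_pair must lie in [-1, 1]")
  if (cfg$n_pairs < 1 || cfg$n_years < 1) stop("n_pairs and n_years must be >= 1")
  # stage windows ordered, checked against an arbitrary season year
  w <- season_anchor_dates(cfg, 2000L)
  if (!(w$incubation_start < w$mean_hatch && w$mean_hatch <= w$brooding_end)) {
    stop("stage windows must satisfy incubation start < mean hatch <= brooding end")
  }
  invisible(cfg)
}

# Resolve the month-day anchors against a season year (the season is labelled
# by its December; hatch and brooding end fall in the next calendar year).
season_anchor_dates <- function(cfg, season_year) {
  list(
    incubation_start = as.POSIXct(paste0(season_year, "-", cfg$season_start_md),
                                  tz = "UTC"),
    mean_hatch = as.POSIXct(paste0(season_year + 1L, "-", cfg$mean_hatch_md),
                            tz = "UTC"),
    brooding_end = as.POSIXct(paste0(season_year + 1L, "-", cfg$brooding_end_md),
                              tz = "UTC")
  )
}

#' Draw a table of pair-season traits
#'
#' Generates one row per monitored pair-season: bird identities, the tagged
#' member's sex, centred boldness scores, ages drawn from the colony age
#' distribution (truncated to 7--42 years), and a new-partnership flag.
#'
#' @param config A [sim_config()] object.
#' @param prop_new_partner Probability that a pair-season is a first breeding
#'   attempt together.
#' @return A tibble with columns `pair_id`, `year`, `tagged_id`, `partner_id`,
#'   `tagged_sex`, `partner_sex`, `boldness_tagged`, `boldness_partner`,
#'   `age_tagged`, `age_partner`, `new_partner`.
#' @export
make_pair_traits <- function(config, prop_new_partner = 0.2) {
  n <- config$n_pairs
  years <- 2008L + sort(sample.int(config$n_years, n, replace = TRUE)) - 1L
  draw_age <- function(k) {
    a <- round(rnorm(k, config$age_mean, config$age_sd))
    pmin(pmax(a, 7L), 42L)
  }
  tagged_sex <- sample(c("F", "M"), n, replace = TRUE)
  tibble::tibble(
    pair_id = sprintf("P%03d", seq_len(n)),
    year = years,
    tagged_id = sprintf("P%03d_T", seq_len(n)),
    partner_id = sprintf("P%03d_U", seq_len(n)),
    tagged_sex = tagged_sex,
    partner_sex = ifelse(tagged_sex == "F", "M", "F"),
    boldness_tagged = rnorm(n),
    boldness_partner = rnorm(n),
    age_tagged = draw_age(n),
    age_partner = draw_age(n),
    new_partner = runif(n) < prop_new_partner
  )
}
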