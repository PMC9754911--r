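#' Simulate one pair-season of alternating foraging trips
#'
#' Builds the alternating one-at-sea / one-on-nest schedule of a breeding pair
#' from incubation start to the end of brooding. Trip durations are generated
#' on the square-root-hours scale: each new trip's sqrt-duration is the stage
#' intercept plus trait effects, plus the coordination response to the
#' partner's previous-trip deviation (computed with the same expanding-window
#' rule the analysis uses), plus pair, year and residual effects; the result
#' is squared and floored at `config$min_trip_h`. Nest reliefs are separated
#' by an exponential overlap lag during which both birds are on land.
#'
#' @param config A [sim_config()] object.
#' @param pair_traits A single row of [make_pair_traits()] output.
#' @param hatch_date POSIXct hatch date for this pair-season; defaults to the
#'   configured mean hatch date.
#' @param pair_effects Numeric `c(intercept, slope)` random effects for the
#'   pair; defaults to zero.
#' @param year_effect Numeric year random effect; defaults to zero.
#' @return A tibble of trips for both pair members with columns `pair_id`,
#'   `year`, `bird_id`, `role` (`"tagged"`/`"partner"`), `index`, `start`,
#'   `end`, `duration_h`, `stage`, `source = "truth"`, and `dev_true` (the
#'   sqrt-scale partner deviation the trip responded to; `NA` when undefined).
#' @examples
#' cfg <- sim_config(n_pairs = 1, seed = 1, sigma_resid = 0,
#'                   sigma_pair_intercept = 0, sigma_year = 0,
#'                   sigma_pair_slope = 0, overlap_lag_mean_h = 0)
#' set.seed(1)
#' tr <- simulate_pair_season(cfg, make_pair_traits(cfg))
#' table(tr$stage)
#' @export
simulate_pair_season <- function(config, pair_traits,
                                 hatch_date = NULL,
                                 pair_effects = c(0, 0),
                                 year_effect = 0) {
  stopifnot(inherits(config, "sim_config"), nrow(pair_traits) == 1)
  tr <- as.list(pair_traits)
  needed <- c("tagged_sex", "partner_sex", "boldness_tagged", "boldness_partner",
              "age_tagged", "age_partner", "new_partner")
  miss <- needed[vapply(tr[needed], function(x) is.null(x) || is.na(x), TRUE)]
  if (length(miss) > 0) {
    stop("incomplete pair traits: ", paste(miss, collapse = ", "))
  }
  anchors <- season_anchor_dates(config, tr$year)
  if (is.null(hatch_date)) hatch_date <- anchors$mean_hatch
  b <- config$beta
  zage <- function(a) (a - config$age_mean) / config$age_sd

  # per-role covariate blocks; the forager is the "focal" bird of its own trips
  role_covs <- list(
    tagged = list(
      sex = tr$tagged_sex, fb = tr$boldness_tagged, pb = tr$boldness_partner,
      fa = zage(tr$age_tagged), pa = zage(tr$age_partner)
    ),
    partner = list(
      sex = tr$partner_sex, fb = tr$boldness_partner, pb = tr$boldness_tagged,
      fa = zage(tr$age_partner), pa = zage(tr$age_tagged)
    )
  )

  # expanding sqrt-duration histories per bird and stage, for the deviation term
  hist <- list(tagged = list(incubation = numeric(), brooding = numeric()),
               partner = list(incubation = numeric(), brooding = numeric()))

  # per-role fixed part of the predictor, constant within a stage
  base_mu <- function(role, stage) {
    cv <- role_covs[[role]]
    terms <- c(
      intercept = if (stage == "incubation") b$intercept_incubation else b$intercept_brooding,
      sex_male = b$sex_male * (cv$sex == "M"),
      focal_boldness = b$focal_boldness * cv$fb,
      partner_boldness = b$partner_boldness * cv$pb,
      focal_age = b$focal_age * cv$fa,
      focal_age_sq = b$focal_age_sq * cv$fa^2,
      partner_age = b$partner_age * cv$pa,
      partner_age_sq = b$partner_age_sq * cv$pa^2,
      new_partner = b$new_partner * tr$new_partner,
      pair = pair_effects[1],
      year = year_effect
    )
    if (any(!is.finite(terms))) {
      stop("non-finite linear predictor term(s): ",
           paste(names(terms)[!is.finite(terms)], collapse = ", "))
    }
    sum(terms)
  }
  mu0 <- list(
    tagged = list(incubation = base_mu("tagged", "incubation"),
                  brooding = base_mu("tagged", "brooding")),
    partner = list(incubation = base_mu("partner", "incubation"),
                   brooding = base_mu("partner", "brooding"))
  )
  if (!is.finite(b$date) || !is.finite(b$coord)) {
    stop("non-finite linear predictor term(s): ",
         paste(c("date", "coord")[!is.finite(c(b$date, b$coord))], collapse = ", "))
  }

  cap <- 400L  # generous upper bound on trips per pair-season
  v_role <- character(cap); v_start <- numeric(cap); v_dur <- numeric(cap)
  v_stage <- character(cap); v_dev <- numeric(cap)
  forager <- sample(c("tagged", "partner"), 1)
  t0 <- as.numeric(anchors$incubation_start)
  t_end <- as.numeric(anchors$brooding_end)
  t_hatch <- as.numeric(hatch_date)
  t_now <- t0
  i <- 0L
  while (t_now < t_end && i < cap) {
    stage <- if (t_now < t_hatch) "incubation" else "brooding"
    other <- if (forager == "tagged") "partner" else "tagged"
    h <- hist[[other]][[stage]]
    dev <- if (length(h) >= 2) h[length(h)] - mean(h[-length(h)]) else NA_real_
    date_z <- ((t_now - t0) / 86400 - config$date_center_d) / config$date_scale_d
    mu <- mu0[[forager]][[stage]] + b$date * date_z +
      (b$coord + pair_effects[2]) * (if (is.na(dev)) 0 else dev) +
      rnorm(1, 0, config$sigma_resid[[stage]])
    dur_h <- max(mu, sqrt(config$min_trip_h))^2
    i <- i + 1L
    v_role[i] <- forager; v_start[i] <- t_now; v_dur[i] <- dur_h
    v_stage[i] <- stage; v_dev[i] <- dev
    hist[[forager]][[stage]] <- c(hist[[forager]][[stage]], sqrt(dur_h))
    lag_h <- if (config$overlap_lag_mean_h > 0) rexp(1, 1 / config$overlap_lag_mean_h) else 0
    t_now <- t_now + (dur_h + lag_h) * 3600
    forager <- other
  }
  idx <- seq_len(i)
  out <- tibble::tibble(
    pair_id = tr$pair_id, year = tr$year,
    bird_id = ifelse(v_role[idx] == "tagged", tr$tagged_id, tr$partner_id),
    role = v_role[idx],
    start = as.POSIXct(v_start[idx], origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(v_start[idx] + v_dur[idx] * 3600, origin = "1970-01-01",
                     tz = "UTC"),
    duration_h = v_dur[idx], stage = v_stage[idx], source = "truth",
    dev_true = v_dev[idx]
  )
  if (nrow(out) > 0) {
    out <- out |>
      dplyr::group_by(.data$bird_id) |>
      dplyr::mutate(index = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::relocate("index", .after = "role")
  }
  out
}

#' Simulate a full multi-pair logger study
#'
#' Draws pair and year random effects, a true hatch date per pair-season, and
#' generates every pair's alternating trip schedule with
#' [simulate_pair_season()]. This is the ground truth against which the
#' segmentation, phenology, feature and model layers can be validated.
#'
#' @param config A [sim_config()] object; `config$seed` (if non-`NULL`) seeds
#'   the RNG so the whole study is reproducible.
#' @param traits Optional pair-season trait table; defaults to
#'   [make_pair_traits()].
#' @return An object of class `"sim_study"`: a list with `trips` (all true
#'   trips), `traits`, `hatch` (pair_id, year, hatch_date), and `config`.
#' @examples
#' st <- simulate_study(sim_config(n_pairs = 3, seed = 7))
#' dplyr::count(st$trips, stage)
#' @export
simulate_study <- function(config, traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(traits)) traits <- make_pair_traits(config)

  # correlated pair intercept/slope effects
  n <- nrow(traits)
  z1 <- rnorm(n); z2 <- rnorm(n)
  pair_int <- config$sigma_pair_intercept * z1
  pair_slo <- config$sigma_pair_slope *
    (config$rho_pair * z1 + sqrt(1 - config$rho_pair^2) * z2)
  year_levels <- sort(unique(traits$year))
  year_eff <- setNames(rnorm(length(year_levels), 0, config$sigma_year), year_levels)

  hatch <- traits |>
    dplyr::mutate(
      hatch_date = purrr::map2_vec(.data$year, rnorm(n, 0, config$hatch_sd_days),
        function(y, jit) {
          anchors <- season_anchor_dates(config, y)
          h <- anchors$mean_hatch + round(jit) * 86400
          # keep the hatch inside the season so windows stay ordered
          pmin(pmax(h, anchors$incubation_start + 30 * 86400),
               anchors$brooding_end - 5 * 86400)
        })
    ) |>
    dplyr::select("pair_id", "year", "hatch_date")

  trips <- purrr::map(seq_len(n), function(i) {
    simulate_pair_season(
      config, traits[i, ],
      hatch_date = hatch$hatch_date[i],
      pair_effects = c(pair_int[i], pair_slo[i]),
      year_effect = year_eff[[as.character(traits$year[i])]]
    )
  }) |>
    dplyr::bind_rows()

  structure(list(trips = trips, traits = traits, hatch = hatch, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>", nrow(x$traits), "pair-seasons,", nrow(x$trips), "true trips\n")
  print(dplyr::count(x$trips, .data$stage, .data$role), ...)
  invisible(x)
}

#' Write ground-truth trip and shift tables
#'
#' Writes the simulator's true trips, and the true nest shifts implied by them
#' (each bird's on-land interval between consecutive trips of its own), in the
#' same tabular schema the segmentation layer emits, flagged `source =
#' "truth"`.
#'
#' @param trips A true-trip tibble from [simulate_study()] or
#'   [simulate_pair_season()].
#' @param dir Output directory; created if missing.
#' @return Invisibly, a list with the `trips` and `shifts` tibbles written.
#' @export
write_truth_tables <- function(trips, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip_cols <- c("bird_id", "pair_id", "year", "index", "start", "end",
                 "duration_h", "source", "stage")
  trips_out <- if (nrow(trips) == 0) {
    tibble::as_tibble(setNames(rep(list(character(0)), length(trip_cols)), trip_cols))
  } else {
    dplyr::select(trips, dplyr::all_of(trip_cols))
  }
  shifts_out <- true_shifts(trips)
  utils::write.csv(iso_times(trips_out), file.path(dir, "truth_trips.csv"),
                   row.names = FALSE)
  utils::write.csv(iso_times(shifts_out), file.path(dir, "truth_shifts.csv"),
                   row.names = FALSE)
  invisible(list(trips = trips_out, shifts = shifts_out))
}

#' True nest shifts implied by a true trip schedule
#'
#' A bird's shift is the land-bound interval between the end of one of its
#' trips and the start of its next trip.
#'
#' @param trips True-trip tibble.
#' @return Tibble with `bird_id`, `pair_id`, `year`, `start`, `end`,
#'   `duration_h`, `source`.
#' @export
true_shifts <- function(trips) {
  if (nrow(trips) == 0) {
    return(tibble::tibble(bird_id = character(0), pair_id = character(0),
                          year = integer(0), start = as.POSIXct(character(0), tz = "UTC"),
                          end = as.POSIXct(character(0), tz = "UTC"),
                          duration_h = numeric(0), source = character(0)))
  }
  trips |>
    dplyr::arrange(.data$bird_id, .data$start) |>
    dplyr::group_by(.data$bird_id, .data$pair_id, .data$year) |>
    dplyr::reframe(
      shift_start = .data$end[-dplyr::n()],
      shift_end = .data$start[-1]
    ) |>
    dplyr::rename(start = "shift_start", end = "shift_end") |>
    dplyr::mutate(
      duration_h = as.numeric(difftime(.data$end, .data$start, units = "hours")),
      source = "truth"
    )
}

# format POSIXct columns as ISO8601 UTC strings for plain-text output
iso_times <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(function(x) inherits(x, "POSIXct")),
    function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ))
}
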