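# Independent oracles and fixture builders shared across tests.

T0 <- as.POSIXct("2011-01-01 00:00:00", tz = "UTC")

# Build an alternating bout tibble from a vector of durations (hours) and the
# state of the first bout.
make_bouts <- function(durations_h, first_state = "dry", bird_id = "b1",
                       t0 = T0) {
  states <- rep(c(first_state, setdiff(c("wet", "dry"), first_state)),
                length.out = length(durations_h))
  ends <- t0 + cumsum(durations_h) * 3600
  starts <- c(t0, head(ends, -1))
  tibble::tibble(bird_id = bird_id, state = states, start = starts,
                 end = ends, duration_h = durations_h)
}

# Random alternating bout sequence with a mix of flight-length and
# land-length dry bouts.
random_bouts <- function(n_bouts = NULL, bird_id = "b1") {
  n_bouts <- n_bouts %||% sample(5:40, 1)
  durations <- numeric(n_bouts)
  first_state <- sample(c("wet", "dry"), 1)
  states <- rep(c(first_state, setdiff(c("wet", "dry"), first_state)),
                length.out = n_bouts)
  for (i in seq_len(n_bouts)) {
    durations[i] <- if (states[i] == "wet") {
      stats::rexp(1, 1 / 3)
    } else if (stats::runif(1) < 0.35) {
      stats::runif(1, 12, 120)  # land period (may land exactly on 12 h below)
    } else {
      stats::runif(1, 0.1, 12)  # flight; 12.0 exactly is still flight
    }
  }
  # sprinkle exact boundary values to exercise the strict > 12 h rule
  if (n_bouts > 3 && stats::runif(1) < 0.3) {
    j <- sample(which(states == "dry"), 1)
    durations[j] <- 12
  }
  make_bouts(durations, first_state, bird_id = bird_id)
}

# Brute-force trip extraction: for every wet bout, decide directly from the
# definition whether it opens a trip, and close that trip at the next land
# bout. Independent of the streaming implementation.
bf_trips_shifts <- function(bouts, max_flight_h = 12) {
  b <- bouts[order(bouts$start), ]
  land <- which(b$state == "dry" & b$duration_h > max_flight_h)
  wet <- which(b$state == "wet")
  starts <- b$start[0]; ends <- b$start[0]
  for (i in wet) {
    prev_land <- land[land < i]
    next_land <- land[land > i]
    if (length(prev_land) == 0 || length(next_land) == 0) next
    p <- max(prev_land)
    if (any(wet > p & wet < i)) next  # not the first wet bout after land
    starts <- c(starts, b$start[i])
    ends <- c(ends, b$start[min(next_land)])
  }
  list(
    trips = tibble::tibble(
      start = starts, end = ends,
      duration_h = as.numeric(difftime(ends, starts, units = "hours"))
    ),
    shifts = tibble::tibble(
      start = b$start[land], end = b$end[land], duration_h = b$duration_h[land]
    )
  )
}

# Minimal stand-in for an lmm_fit: enough structure for best_set,
# exclude_nested and model_average.
stub_fit <- function(terms, aicc, estimates = NULL, ses = NULL) {
  if (is.null(estimates)) estimates <- setNames(rep(1, length(terms)), terms)
  if (is.null(ses)) ses <- setNames(rep(0.5, length(estimates)), names(estimates))
  structure(list(
    terms = terms, aicc = aicc,
    coefficients = tibble::tibble(term = names(estimates),
                                  estimate = unname(estimates),
                                  se = unname(ses[names(estimates)]))
  ), class = "lmm_fit")
}

# A small noiseless simulation configuration: all variance components and
# lags zero so schedules are deterministic given the betas.
quiet_config <- function(n_pairs = 2, seed = 1, beta = list(coord = 0), ...) {
  sim_config(n_pairs = n_pairs, seed = seed, beta = beta,
             sigma_pair_intercept = 0, sigma_pair_slope = 0, sigma_year = 0,
             sigma_resid = 0, overlap_lag_mean_h = 0, hatch_sd_days = 0, ...)
}

# Stage windows built from the true hatch dates of a simulated study.
true_windows <- function(study) {
  dplyr::bind_rows(lapply(seq_len(nrow(study$hatch)), function(i) {
    w <- stage_windows(study$hatch$year[i], study$hatch$hatch_date[i])
    w$pair_id <- study$hatch$pair_id[i]
    w$year <- study$hatch$year[i]
    w
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
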