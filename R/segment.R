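#' Parse a binned immersion-logger stream into wet/dry bouts
#'
#' The binned logger dialect records the number of seconds the sensor was wet
#' in each 10-minute bin. A bin is classified wet when its wet seconds
#' strictly exceed the threshold (default 45 s in 10 min); adjacent bins of
#' the same state are merged into maximal bouts.
#'
#' @param stream Tibble with columns `bird_id`, `bin_start_iso8601_utc`
#'   (POSIXct or ISO8601 string) and `wet_seconds`. Several birds may share a
#'   stream; each is parsed separately.
#' @param wet_threshold_s Wet-seconds threshold; strict `>` comparison.
#' @param bin_width_min Bin width in minutes.
#' @return Tibble of bouts: `bird_id`, `state` (`"wet"`/`"dry"`), `start`,
#'   `end`, `duration_h`. Bouts are contiguous and strictly alternate.
#' @examples
#' s <- tibble::tibble(
#'   bird_id = "b1",
#'   bin_start_iso8601_utc = as.POSIXct("2010-01-01", tz = "UTC") +
#'     600 * (0:4),
#'   wet_seconds = c(0, 0, 600, 600, 0)
#' )
#' parse_binned(s)
#' @export
parse_binned <- function(stream, wet_threshold_s = 45, bin_width_min = 10) {
  stream <- normalise_stream(stream, "bin_start_iso8601_utc")
  bin_s <- bin_width_min * 60
  stream |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$bin_start_iso8601_utc)
      t <- as.numeric(df$bin_start_iso8601_utc)
      if (nrow(df) == 0) stop("empty stream for bird ", key$bird_id)
      d <- diff(t)
      if (any(d != bin_s)) {
        bad <- which(d != bin_s)[1]
        at <- if (d[bad] <= 0) df$bin_start_iso8601_utc[bad + 1] else
          df$bin_start_iso8601_utc[bad] + bin_s
        stop(if (d[bad] <= 0) "duplicate bin at " else "gap in bins at ",
             format(at, "%Y-%m-%dT%H:%M:%SZ"), " for bird ", key$bird_id)
      }
      if (any(df$wet_seconds < 0 | df$wet_seconds > bin_s)) {
        stop("wet_seconds outside [0, ", bin_s, "] for bird ", key$bird_id)
      }
      wet <- df$wet_seconds > wet_threshold_s
      r <- rle(wet)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1
      tibble::tibble(
        state = ifelse(r$values, "wet", "dry"),
        start = df$bin_start_iso8601_utc[idx_start],
        end = df$bin_start_iso8601_utc[idx_end] + bin_s,
        duration_h = r$lengths * bin_s / 3600
      )
    }) |>
    dplyr::ungroup()
}

#' Parse a state-change logger stream into wet/dry bouts
#'
#' The state-change dialect records the timestamp of every wet/dry transition.
#' Each bout spans two successive transitions; the final bout is clipped to
#' the deployment end. Consecutive identical states (logger glitches) are
#' merged with a warning.
#'
#' @param stream Tibble with columns `bird_id`, `timestamp_iso8601_utc`
#'   (POSIXct or ISO8601 string) and `new_state` (`"wet"`/`"dry"`).
#' @param deployment_end End of the recording window; defaults to the
#'   stream's `"deployment_end"` attribute, else the last transition (in
#'   which case the final open bout has zero length and is dropped).
#' @return Tibble of bouts as in [parse_binned()].
#' @export
parse_state_change <- function(stream, deployment_end = NULL) {
  deployment_end <- deployment_end %||% attr(stream, "deployment_end")
  stream <- normalise_stream(stream, "timestamp_iso8601_utc")
  stream |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$timestamp_iso8601_utc)
      if (any(diff(as.numeric(df$timestamp_iso8601_utc)) <= 0)) {
        stop("timestamps not strictly increasing for bird ", key$bird_id)
      }
      if (!all(df$new_state %in% c("wet", "dry"))) {
        stop("new_state must be 'wet' or 'dry'")
      }
      dup <- c(FALSE, df$new_state[-1] == df$new_state[-nrow(df)])
      if (any(dup)) {
        warning("merged ", sum(dup), " repeated state record(s) for bird ",
                key$bird_id, call. = FALSE)
        df <- df[!dup, ]
      }
      t_end <- deployment_end %||% df$timestamp_iso8601_utc[nrow(df)]
      starts <- df$timestamp_iso8601_utc
      ends <- c(df$timestamp_iso8601_utc[-1], as.POSIXct(t_end, tz = "UTC"))
      out <- tibble::tibble(
        state = df$new_state, start = starts, end = ends,
        duration_h = as.numeric(difftime(ends, starts, units = "hours"))
      )
      dplyr::filter(out, .data$duration_h > 0)
    }) |>
    dplyr::ungroup()
}

normalise_stream <- function(stream, tcol) {
  if (!all(c("bird_id", tcol) %in% names(stream))) {
    stop("stream must have columns bird_id and ", tcol)
  }
  if (!inherits(stream[[tcol]], "POSIXct")) {
    stream[[tcol]] <- as.POSIXct(stream[[tcol]],
                                 format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  stream
}

#' Extract foraging trips and nest shifts from a bout sequence
#'
#' A dry bout strictly longer than `max_flight_h` (default 12 h, the species'
#' maximum continuous flight time) means the bird was on land: these bouts are
#' nest shifts. A foraging trip runs from the first wet bout after a shift to
#' the start of the next shift; dry bouts of 12 h or less inside that span are
#' flight. Leading and trailing spans not bounded by shifts on both sides are
#' dropped (their durations would be censored by the deployment window).
#'
#' @param bouts Bout tibble from [parse_binned()] or [parse_state_change()].
#' @param max_flight_h Longest dry spell still classified as flight.
#' @return A list with `trips` (tibble: `bird_id`, `index`, `start`, `end`,
#'   `duration_h`, `source = "observed"`) and `shifts` (tibble: `bird_id`,
#'   `start`, `end`, `duration_h`).
#' @examples
#' b <- tibble::tibble(
#'   bird_id = "b1",
#'   state = c("dry", "wet", "dry", "wet", "dry"),
#'   start = as.POSIXct("2010-01-01", tz = "UTC") +
#'     3600 * cumsum(c(0, 13, 2, 1, 3)),
#'   end = as.POSIXct("2010-01-01", tz = "UTC") +
#'     3600 * cumsum(c(13, 2, 1, 3, 14))
#' )
#' b$duration_h <- as.numeric(b$end - b$start, units = "hours")
#' extract_trips_and_shifts(b)$trips
#' @export
extract_trips_and_shifts <- function(bouts, max_flight_h = 12) {
  res <- bouts |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$start)
      if (nrow(df) > 1 && any(df$state[-1] == df$state[-nrow(df)])) {
        stop("bout sequence does not alternate for bird ", key$bird_id)
      }
      is_shift <- df$state == "dry" & df$duration_h > max_flight_h
      shift_idx <- which(is_shift)
      if (length(shift_idx) == 0) {
        warning("no dry bout > ", max_flight_h, " h for bird ", key$bird_id,
                ": no trips extracted", call. = FALSE)
      }
      shifts <- tibble::tibble(
        bird_id = key$bird_id,
        start = df$start[shift_idx], end = df$end[shift_idx],
        duration_h = df$duration_h[shift_idx]
      )
      trips <- list()
      if (length(shift_idx) >= 2) {
        for (j in seq_len(length(shift_idx) - 1)) {
          span <- (shift_idx[j] + 1):(shift_idx[j + 1] - 1)
          wet_in <- span[df$state[span] == "wet"]
          if (length(wet_in) == 0) next
          trips[[length(trips) + 1]] <- tibble::tibble(
            bird_id = key$bird_id,
            start = df$start[wet_in[1]],
            end = df$start[shift_idx[j + 1]]
          )
        }
      }
      trips <- dplyr::bind_rows(trips)
      if (nrow(trips) > 0) {
        trips <- trips |>
          dplyr::mutate(
            duration_h = as.numeric(difftime(.data$end, .data$start, units = "hours")),
            source = "observed", index = dplyr::row_number()
          ) |>
          dplyr::relocate("index", .after = "bird_id")
      } else {
        trips <- tibble::tibble(bird_id = character(0), index = integer(0),
                                start = df$start[0], end = df$start[0],
                                duration_h = numeric(0), source = character(0))
      }
      list(trips = trips, shifts = shifts)
    })
  list(trips = dplyr::bind_rows(purrr::map(res, "trips")),
       shifts = dplyr::bind_rows(purrr::map(res, "shifts")))
}

#' Infer the untagged partner's foraging trips
#'
#' When only one pair member carries a logger, the partner's trips are taken
#' to be the tagged bird's land periods between trips: each inferred trip runs
#' from the end of one observed trip to the start of the next.
#'
#' @param tagged_trips Observed trips of the tagged bird (one bird).
#' @param partner_id Id to assign to the inferred trips.
#' @return Tibble of inferred trips (`source = "inferred"`); `n - 1` trips
#'   from `n` observed ones, empty if fewer than two observed trips.
#' @examples
#' tr <- tibble::tibble(
#'   bird_id = "b1",
#'   start = as.POSIXct("2010-01-01", tz = "UTC") + 3600 * c(0, 250),
#'   end = as.POSIXct("2010-01-01", tz = "UTC") + 3600 * c(100, 330)
#' )
#' infer_partner_trips(tr, partner_id = "b1_mate")$duration_h  # 150
#' @export
infer_partner_trips <- function(tagged_trips, partner_id = NA_character_) {
  stopifnot(length(unique(tagged_trips$bird_id)) <= 1)
  tr <- dplyr::arrange(tagged_trips, .data$start)
  if (nrow(tr) < 2) {
    return(tibble::tibble(bird_id = character(0), index = integer(0),
                          start = tr$start[0], end = tr$start[0],
                          duration_h = numeric(0), source = character(0)))
  }
  out <- tibble::tibble(
    bird_id = partner_id,
    index = seq_len(nrow(tr) - 1),
    start = tr$end[-nrow(tr)],
    end = tr$start[-1]
  )
  extra <- intersect(c("pair_id", "year"), names(tr))
  for (cl in extra) out[[cl]] <- tr[[cl]][-nrow(tr)]
  out |>
    dplyr::mutate(
      duration_h = as.numeric(difftime(.data$end, .data$start, units = "hours")),
      source = "inferred"
    )
}

#' Accuracy of inferred partner trips against ground truth
#'
#' Matches each inferred trip to the true trip of the same bird with maximal
#' temporal overlap, and scores each match as
#' `100 * (1 - |inferred - true| / true)` percent, floored at zero. Unmatched
#' trips on either side are excluded and counted.
#'
#' @param inferred Inferred trip tibble (needs `start`, `end`, `duration_h`;
#'   `pair_id` used for grouping when present).
#' @param truth True trip tibble for the same bird(s).
#' @return One-row tibble: `mean_accuracy_pct`, `sd_accuracy_pct`, `n_matched`,
#'   `n_unmatched`.
#' @export
inference_accuracy <- function(inferred, truth) {
  if (nrow(inferred) == 0 || nrow(truth) == 0) {
    return(tibble::tibble(mean_accuracy_pct = NA_real_, sd_accuracy_pct = NA_real_,
                          n_matched = 0L,
                          n_unmatched = nrow(inferred) + nrow(truth)))
  }
  grp <- if ("pair_id" %in% names(inferred) && "pair_id" %in% names(truth)) {
    intersect(unique(inferred$pair_id), unique(truth$pair_id))
  } else NA_character_
  acc <- c(); n_un <- 0L
  for (g in grp) {
    inf_g <- if (is.na(g)) inferred else dplyr::filter(inferred, .data$pair_id == g)
    tru_g <- if (is.na(g)) truth else dplyr::filter(truth, .data$pair_id == g)
    used <- rep(FALSE, nrow(tru_g))
    for (i in seq_len(nrow(inf_g))) {
      ov <- pmin(as.numeric(inf_g$end[i]), as.numeric(tru_g$end)) -
        pmax(as.numeric(inf_g$start[i]), as.numeric(tru_g$start))
      ov[used] <- -Inf
      j <- which.max(ov)
      if (length(j) == 0 || ov[j] <= 0) {
        n_un <- n_un + 1L
        next
      }
      used[j] <- TRUE
      acc <- c(acc, 100 * max(0, 1 - abs(inf_g$duration_h[i] - tru_g$duration_h[j]) /
                                tru_g$duration_h[j]))
    }
    n_un <- n_un + sum(!used)
  }
  tibble::tibble(
    mean_accuracy_pct = if (length(acc)) mean(acc) else NA_real_,
    sd_accuracy_pct = if (length(acc) > 1) sd(acc) else NA_real_,
    n_matched = length(acc), n_unmatched = n_un
  )
}

#' Nest overlap at relief events in dual-tagged pairs
#'
#' When both pair members carry loggers, the delay between the returning
#' bird's arrival and its partner's departure is observable. For each pair of
#' consecutive trips by different birds, the overlap is the later trip's start
#' minus the earlier trip's end, floored at zero, and is summarised per
#' breeding stage as a mean in hours and as a percentage of the stage's mean
#' trip duration.
#'
#' @param trips Observed trips of both pair members, with a `stage` column
#'   (overlap events take the stage of the departing trip). Several pairs may
#'   be passed together when a `pair_id` column is present; relief events are
#'   then measured within pairs and pooled.
#' @return Tibble per stage: `stage`, `mean_overlap_h`, `pct_of_mean_trip`,
#'   `n_events`.
#' @export
nest_overlap <- function(trips) {
  stopifnot(all(c("bird_id", "start", "end", "duration_h") %in% names(trips)))
  if (!"stage" %in% names(trips)) trips$stage <- "unassigned"
  if (!"pair_id" %in% names(trips)) trips$pair_id <- "pair"
  relief <- trips |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::group_map(function(tr, key) {
      tr <- dplyr::arrange(tr, .data$start)
      if (nrow(tr) < 2) return(NULL)
      k <- seq_len(nrow(tr) - 1)
      tibble::tibble(
        overlap_h = pmax(0, as.numeric(difftime(tr$start[k + 1], tr$end[k],
                                                units = "hours"))),
        stage = tr$stage[k + 1],
        different_birds = tr$bird_id[k + 1] != tr$bird_id[k]
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(relief) == 0) {
    return(tibble::tibble(stage = character(0), mean_overlap_h = numeric(0),
                          pct_of_mean_trip = numeric(0), n_events = integer(0)))
  }
  relief <- dplyr::filter(relief, .data$different_birds)
  stage_means <- trips |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(mean_trip_h = mean(.data$duration_h), .groups = "drop")
  relief |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(mean_overlap_h = mean(.data$overlap_h),
                     n_events = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(stage_means, by = "stage") |>
    dplyr::mutate(pct_of_mean_trip = 100 * .data$mean_overlap_h / .data$mean_trip_h) |>
    dplyr::select("stage", "mean_overlap_h", "pct_of_mean_trip", "n_events")
}
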