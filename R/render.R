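#' Render a bird's schedule into a raw immersion-logger stream
#'
#' Turns a true trip schedule into the raw stream an immersion logger would
#' have recorded for one bird: at-sea intervals are filled with alternating
#' on-water (wet) and flight (dry) bouts — exponential lengths, flight bouts
#' truncated below 12 h — while on-land intervals are fully dry. The stream is
#' emitted in either logger dialect: per-bin wet seconds (10-min bins) or
#' timestamped wet/dry state changes.
#'
#' @param trips True-trip tibble for a single pair-season (both birds may be
#'   present; only `bird`'s trips are rendered).
#' @param bird Bird id to render.
#' @param config A [sim_config()] object (dialect, bin width, bout settings).
#' @param dialect Overrides `config$logger_dialect` if given.
#' @param deployment_start,deployment_end Deployment window; defaults bracket
#'   the bird's trips by 15 h of dry record on each side so the first and last
#'   trips are bounded by land periods.
#' @return A tibble: binned dialect has columns `bird_id`,
#'   `bin_start_iso8601_utc` (POSIXct), `wet_seconds`; state-change dialect
#'   has `bird_id`, `timestamp_iso8601_utc` (POSIXct), `new_state`. The
#'   dialect and deployment window are attached as attributes.
#' @examples
#' cfg <- sim_config(n_pairs = 1, seed = 2)
#' st <- simulate_study(cfg)
#' s <- render_logger_stream(st$trips, st$traits$tagged_id[1], cfg)
#' head(s)
#' @export
render_logger_stream <- function(trips, bird, config,
                                 dialect = NULL,
                                 deployment_start = NULL,
                                 deployment_end = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dialect <- dialect %||% config$logger_dialect
  dialect <- match.arg(dialect, c("binned", "state_change"))
  mine <- trips |>
    dplyr::filter(.data$bird_id == bird) |>
    dplyr::arrange(.data$start)
  if (nrow(mine) > 0 && any(diff(as.numeric(mine$start)) <= 0)) {
    stop("trips of bird ", bird, " are not strictly ordered")
  }
  if (nrow(mine) > 1 &&
      any(as.numeric(mine$start[-1]) < as.numeric(mine$end[-nrow(mine)]))) {
    stop("overlapping trips for bird ", bird, " beyond configured lags")
  }
  deployment_start <- deployment_start %||%
    (if (nrow(mine) > 0) min(mine$start) - 15 * 3600 else NULL)
  deployment_end <- deployment_end %||%
    (if (nrow(mine) > 0) max(mine$end) + 15 * 3600 else NULL)
  if (is.null(deployment_start) || is.null(deployment_end)) {
    stop("no trips for bird ", bird, " and no deployment window given")
  }

  wet <- dplyr::bind_rows(purrr::map2(mine$start, mine$end, function(s, e) {
    trip_wet_intervals(as.numeric(s), as.numeric(e), config)
  }))

  out <- if (dialect == "binned") {
    bins_to_tibble(bird, wet, as.numeric(deployment_start),
                   as.numeric(deployment_end), config$bin_width_min * 60)
  } else {
    transitions_to_tibble(bird, wet, as.numeric(deployment_start))
  }
  attr(out, "dialect") <- dialect
  attr(out, "deployment_start") <- deployment_start
  attr(out, "deployment_end") <- deployment_end
  out
}

# alternating wet/flight bouts within one at-sea interval [s, e] (seconds);
# a trip starts and ends with a wet (on-water) bout, and every wet bout is at
# least min_wet_bout_h long so both logger dialects register it
trip_wet_intervals <- function(s, e, config) {
  min_wet <- config$min_wet_bout_h * 3600
  wet_extra_mean <- (config$trip_wet_mean_h - config$min_wet_bout_h) * 3600
  dry_mean <- config$trip_dry_mean_h * 3600
  dry_max <- config$trip_dry_max_h * 3600
  ws <- numeric(); we <- numeric()
  t <- s
  repeat {
    w_end <- min(t + min_wet + rexp(1, 1 / wet_extra_mean), e)
    ws <- c(ws, t); we <- c(we, w_end)
    if (w_end >= e) break
    d_len <- min(rexp(1, 1 / dry_mean), dry_max)
    t2 <- w_end + d_len
    if (e - t2 < min_wet) {
      we[length(we)] <- e  # no room for another full wet bout: absorb the flight
      break
    }
    t <- t2
  }
  tibble::tibble(wet_start = ws, wet_end = we)
}

bins_to_tibble <- function(bird, wet, t0, t1, bin_s) {
  n_bins <- ceiling((t1 - t0) / bin_s)
  wet_sec <- numeric(n_bins)
  if (nrow(wet) > 0) {
    for (i in seq_len(nrow(wet))) {
      a <- max(wet$wet_start[i], t0); b <- min(wet$wet_end[i], t0 + n_bins * bin_s)
      if (b <= a) next
      i0 <- floor((a - t0) / bin_s); i1 <- floor((b - t0 - 1e-9) / bin_s)
      for (k in i0:i1) {
        lo <- t0 + k * bin_s; hi <- lo + bin_s
        wet_sec[k + 1] <- wet_sec[k + 1] + (min(b, hi) - max(a, lo))
      }
    }
  }
  tibble::tibble(
    bird_id = bird,
    bin_start_iso8601_utc = as.POSIXct(t0 + (seq_len(n_bins) - 1) * bin_s,
                                       origin = "1970-01-01", tz = "UTC"),
    wet_seconds = wet_sec
  )
}

transitions_to_tibble <- function(bird, wet, t0) {
  if (nrow(wet) == 0) {
    return(tibble::tibble(
      bird_id = bird,
      timestamp_iso8601_utc = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
      new_state = "dry"
    ))
  }
  times <- c(t0, rbind(wet$wet_start, wet$wet_end))
  states <- c("dry", rep(c("wet", "dry"), nrow(wet)))
  # if a wet interval starts exactly at t0, keep the wet row, not the dry one
  keep <- !duplicated(times, fromLast = TRUE)
  tibble::tibble(
    bird_id = bird,
    timestamp_iso8601_utc = as.POSIXct(times[keep], origin = "1970-01-01", tz = "UTC"),
    new_state = states[keep]
  )
}

#' Write / read a logger stream as TSV
#'
#' Streams are stored as tab-separated text with ISO8601 UTC timestamps;
#' columns are `bird_id`, `bin_start_iso8601_utc`, `wet_seconds` for the
#' binned dialect and `bird_id`, `timestamp_iso8601_utc`, `new_state` for the
#' state-change dialect. [read_logger_stream()] infers the dialect from the
#' header.
#'
#' @param stream A stream tibble from [render_logger_stream()].
#' @param path File path.
#' @return `write_logger_stream()`: the path, invisibly.
#'   `read_logger_stream()`: the stream tibble with a `"dialect"` attribute.
#' @export
write_logger_stream <- function(stream, path) {
  utils::write.table(iso_times(stream), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_logger_stream
#' @export
read_logger_stream <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  tcol <- intersect(c("bin_start_iso8601_utc", "timestamp_iso8601_utc"), names(df))
  if (length(tcol) != 1) {
    stop("unrecognised logger stream header in ", path)
  }
  df[[tcol]] <- as.POSIXct(df[[tcol]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  attr(df, "dialect") <- if (tcol == "bin_start_iso8601_utc") "binned" else "state_change"
  df
}
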