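#' Breeding-stage windows for a season
#'
#' The season is labelled by the December in which incubation begins:
#' incubation starts on 16 December (the earliest lay date), hatch is either
#' detected per pair from the drop in trip duration or falls back to the
#' colony mean of 15 March, and brooding ends on 11 April.
#'
#' @param season_year Integer year of the season's December.
#' @param hatch_date Detected hatch (POSIXct) or `NULL` to use the fallback.
#' @param incubation_start_md,fallback_hatch_md,brooding_end_md Month-day
#'   anchors (`"mm-dd"`).
#' @return One-row tibble: `season_year`, `incubation_start`, `hatch_date`,
#'   `hatch_source` (`"detected"`/`"fallback"`), `brooding_end`.
#' @examples
#' stage_windows(2010)
#' @export
stage_windows <- function(season_year, hatch_date = NULL,
                          incubation_start_md = "12-16",
                          fallback_hatch_md = "03-15",
                          brooding_end_md = "04-11") {
  inc <- as.POSIXct(paste0(season_year, "-", incubation_start_md), tz = "UTC")
  brood_end <- as.POSIXct(paste0(season_year + 1, "-", brooding_end_md), tz = "UTC")
  src <- if (is.null(hatch_date) || is.na(hatch_date)) "fallback" else "detected"
  hatch <- if (src == "fallback") {
    as.POSIXct(paste0(season_year + 1, "-", fallback_hatch_md), tz = "UTC")
  } else {
    as.POSIXct(hatch_date, tz = "UTC")
  }
  if (!(inc < hatch && hatch <= brood_end)) {
    stop("stage windows out of order: need incubation start < hatch <= brooding end")
  }
  tibble::tibble(season_year = season_year, incubation_start = inc,
                 hatch_date = hatch, hatch_source = src, brooding_end = brood_end)
}

#' Detect a pair's hatch date from the drop in trip duration
#'
#' Hatching ends incubation's long foraging trips: brooding trips are less
#' than half as long on average. Within a search window the series of trip
#' durations is split at the single change-point that minimises the pooled
#' within-segment sum of squares of log duration; the split is accepted only
#' if the mean post-split duration is below `ratio_threshold` times the mean
#' pre-split duration. The hatch date is the start of the first post-split
#' trip.
#'
#' @param trips Trip tibble for one pair-season (observed and inferred trips
#'   may be combined for better temporal resolution); needs `start` and
#'   `duration_h`.
#' @param search_start,search_end Search window; defaults 1 February to
#'   11 April of the season following `season_year`.
#' @param season_year Season label used to build the default window; inferred
#'   from the earliest trip when missing (a December trip belongs to its own
#'   calendar year's season, later trips to the previous year's).
#' @param ratio_threshold Acceptance ratio for post/pre mean duration.
#' @param min_trips Minimum trips inside the window to attempt detection.
#' @return One-row tibble: `hatch_date` (POSIXct or `NA`), `detected`
#'   (logical), `reason` (`NA` when detected), `ratio` (post/pre mean ratio at
#'   the chosen split, `NA` if not computed).
#' @examples
#' tr <- tibble::tibble(
#'   start = as.POSIXct("2011-02-10", tz = "UTC") + 86400 * (0:5) * 6,
#'   duration_h = c(130, 140, 120, 60, 58, 62)
#' )
#' detect_hatch(tr, season_year = 2010)
#' @export
detect_hatch <- function(trips, search_start = NULL, search_end = NULL,
                         season_year = NULL, ratio_threshold = 0.6,
                         min_trips = 4) {
  none <- function(reason, ratio = NA_real_) {
    tibble::tibble(hatch_date = as.POSIXct(NA, tz = "UTC"), detected = FALSE,
                   reason = reason, ratio = ratio)
  }
  if (nrow(trips) == 0) return(none("no trips"))
  if (is.null(season_year)) {
    first <- min(trips$start)
    season_year <- as.integer(format(first, "%Y")) -
      (as.integer(format(first, "%m")) < 12)
  }
  search_start <- search_start %||%
    as.POSIXct(paste0(season_year + 1, "-02-01"), tz = "UTC")
  search_end <- search_end %||%
    as.POSIXct(paste0(season_year + 1, "-04-11"), tz = "UTC")

  tr <- trips |>
    dplyr::filter(.data$start >= search_start, .data$start <= search_end) |>
    dplyr::arrange(.data$start)
  n <- nrow(tr)
  if (n < min_trips) return(none(paste0("fewer than ", min_trips, " trips in window")))
  if (any(tr$duration_h <= 0)) return(none("non-positive trip duration"))

  y <- log(tr$duration_h)
  ss <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  splits <- seq_len(n - 1)  # last index of the pre-split segment
  pooled <- vapply(splits, function(k) ss(y[1:k]) + ss(y[(k + 1):n]), numeric(1))
  k <- splits[which.min(pooled)]
  ratio <- mean(tr$duration_h[(k + 1):n]) / mean(tr$duration_h[1:k])
  if (ratio >= ratio_threshold) {
    return(none("post/pre duration ratio above threshold", ratio))
  }
  tibble::tibble(hatch_date = tr$start[k + 1], detected = TRUE,
                 reason = NA_character_, ratio = ratio)
}

#' Assign breeding stages to trips
#'
#' A trip's stage is the window containing its start time: incubation from
#' incubation start (exclusive of hatch), brooding from hatch through the end
#' of brooding. Trips starting after the end of brooding, or before
#' incubation start, are `"unassigned"` and excluded from downstream models.
#'
#' @param trips Trip tibble with `start` (and `pair_id`/`year` if `windows`
#'   has several rows).
#' @param windows Window tibble from [stage_windows()]; when it carries
#'   `pair_id`/`year` columns, trips are matched to their own pair-season
#'   windows.
#' @return `trips` with a `stage` column.
#' @export
assign_stages <- function(trips, windows) {
  keys <- intersect(c("pair_id", "year"), intersect(names(trips), names(windows)))
  joined <- if (length(keys) > 0) {
    dplyr::left_join(trips, windows, by = keys)
  } else {
    stopifnot(nrow(windows) == 1)
    dplyr::cross_join(trips, windows)
  }
  out <- joined |>
    dplyr::mutate(stage = dplyr::case_when(
      .data$start >= .data$incubation_start & .data$start < .data$hatch_date ~ "incubation",
      .data$start >= .data$hatch_date & .data$start <= .data$brooding_end ~ "brooding",
      TRUE ~ "unassigned"
    ))
  dplyr::select(out, dplyr::all_of(names(trips)[names(trips) != "stage"]), "stage")
}

#' Detect hatch dates for every pair-season and build stage windows
#'
#' Runs [detect_hatch()] per pair-season on the combined observed and
#' inferred trips, and falls back to the mean hatch date where detection
#' fails. The returned table records which pairs were detected versus
#' fallback.
#'
#' @param trips Trip tibble with `pair_id`, `year`, `start`, `duration_h`.
#' @param ratio_threshold,min_trips Passed to [detect_hatch()].
#' @return Windows tibble: one row per pair-season with `pair_id`, `year` and
#'   the [stage_windows()] columns.
#' @export
build_stage_windows <- function(trips, ratio_threshold = 0.6, min_trips = 4) {
  trips |>
    dplyr::group_by(.data$pair_id, .data$year) |>
    dplyr::group_modify(function(df, key) {
      det <- detect_hatch(df, season_year = key$year[1],
                          ratio_threshold = ratio_threshold, min_trips = min_trips)
      stage_windows(key$year[1],
                    hatch_date = if (det$detected) det$hatch_date else NULL) |>
        dplyr::select(-"season_year")
    }) |>
    dplyr::ungroup()
}
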