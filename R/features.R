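#' Partner previous-trip deviation
#'
#' The coordination covariate: for each trip in a partner's in-stage series,
#' the deviation of that trip's duration from the expanding mean of the
#' partner's earlier trips in the same stage. The first trip of a stage has no
#' earlier trips and its deviation is undefined (`NA`). The focal trip that
#' follows partner trip *i* receives deviation *i*; a positive focal response
#' to this covariate means the focal bird lengthens its own trip after an
#' unusually long partner trip, i.e. the pair coordinates.
#'
#' @param durations Numeric vector of one partner's trip durations, ordered in
#'   time within one breeding stage (any scale; hours or sqrt-hours).
#' @return Numeric vector of the same length; element 1 is `NA`.
#' @examples
#' partner_prev_deviation(c(100, 120, 140))  # NA, +20, +30
#' @export
partner_prev_deviation <- function(durations) {
  n <- length(durations)
  if (n == 0) return(numeric(0))
  run_mean <- cumsum(durations) / seq_len(n)
  c(NA_real_, durations[-1] - run_mean[-n])
}

#' Collapse extreme age categories
#'
#' Sparse extreme ages invite spurious quadratic age effects. Working inward
#' from each end of the age distribution, extreme values are merged into the
#' adjacent value until the boundary categories each hold at least
#' `min_count` distinct birds; interior ages are untouched.
#'
#' @param ages Integer ages, one element per record (may repeat per trip).
#' @param bird_id Optional ids parallel to `ages`; birds are counted uniquely.
#'   When omitted every element counts as its own bird.
#' @param min_count Minimum number of birds in each boundary category.
#' @return Collapsed ages, same length as `ages`, with attributes
#'   `lower_bound` and `upper_bound`.
#' @examples
#' collapse_ages(c(7, 8, 8, 9, 10, 10, 10, 11, 12, 12, 12, 12, 12))
#' @export
collapse_ages <- function(ages, bird_id = NULL, min_count = 5) {
  if (length(ages) == 0) return(ages)
  if (is.null(bird_id)) bird_id <- seq_along(ages)
  per_bird <- tibble::tibble(bird = bird_id, age = ages) |>
    dplyr::distinct() |>
    dplyr::count(.data$age) |>
    dplyr::arrange(.data$age)
  if (sum(per_bird$n) < min_count) {
    warning("fewer than ", min_count, " birds in total; ages not collapsed",
            call. = FALSE)
    return(structure(ages, lower_bound = min(ages), upper_bound = max(ages)))
  }
  lo <- per_bird$age[which(cumsum(per_bird$n) >= min_count)[1]]
  hi <- per_bird$age[rev(which(rev(cumsum(rev(per_bird$n))) >= min_count))[1]]
  if (lo > hi) {
    warning("age distribution too narrow to hold ", min_count,
            " birds at both extremes; ages not collapsed", call. = FALSE)
    return(structure(ages, lower_bound = min(ages), upper_bound = max(ages)))
  }
  structure(pmin(pmax(ages, lo), hi), lower_bound = lo, upper_bound = hi)
}

#' Build the stage-specific model tables
#'
#' Joins trips, traits and stage windows into the analysis-ready table: the
#' response is the square root of focal trip duration in hours; the
#' coordination covariate is the partner's previous-trip deviation; date is
#' days since incubation start; extreme ages are collapsed per stage subset;
#' continuous covariates are scaled to mean 0, SD 1 on the pooled table
#' before the stage split; quadratic age terms are squares of the scaled
#' linear terms. Row filters, each itemised in the manifest: trips outside
#' the stage windows, rows with an undefined deviation, the first brooding
#' row of each pair-season (its partner deviation refers to incubation), and
#' — in dual-tagged pairs — trips of the second-tagged bird.
#'
#' @param trips Trip tibble (`pair_id`, `year`, `bird_id`, `start`, `end`,
#'   `duration_h`, `source`, optionally `role`). Focal rows are observed
#'   (tagged-bird) trips; partner rows are inferred trips or, for simulated
#'   truth, the partner's true trips.
#' @param traits Pair-season trait table as from [make_pair_traits()] (real
#'   data needs the same columns; boldness columns hold [score_boldness()]
#'   scores).
#' @param windows Stage-window tibble from [build_stage_windows()] (or
#'   [stage_windows()] rows carrying `pair_id`/`year`).
#' @param dev_on Scale on which the deviation is computed: `"hours"` (the
#'   analysis default) or `"sqrt"` (the generative parameterisation, useful
#'   for parameter-recovery studies).
#' @param scale_covariates Scale continuous covariates (pooled, pre-split)?
#' @param focal_roles Which roles contribute focal rows when a `role` column
#'   is present; `c("tagged", "partner")` uses both pair members as focal
#'   birds (simulated data, where both schedules are known).
#' @param min_age_count Boundary size for [collapse_ages()].
#' @param drop_first_brooding Drop each pair-season's first brooding row?
#' @return A `trip_model_table`: list with tibbles `incubation` and
#'   `brooding` (columns `response`, `sex`, `new_partner`, `focal_boldness`,
#'   `partner_boldness`, `focal_age`, `focal_age_sq`, `partner_age`,
#'   `partner_age_sq`, `date`, `partner_prev_dev`, `pair_id`, `year`,
#'   `stage`) and `manifest` (scaling constants, collapsing bounds, itemised
#'   exclusion counts).
#' @export
build_model_table <- function(trips, traits, windows,
                              dev_on = c("hours", "sqrt"),
                              scale_covariates = TRUE,
                              focal_roles = "tagged",
                              min_age_count = 5,
                              drop_first_brooding = TRUE) {
  dev_on <- match.arg(dev_on)
  excl <- list()

  tr <- assign_stages(trips, windows)

  # identify focal vs partner rows
  if ("role" %in% names(tr)) {
    focal <- dplyr::filter(tr, .data$role %in% focal_roles)
    partner_src <- tr  # partner series = the other bird's own rows
  } else {
    focal <- dplyr::filter(tr, .data$source == "observed")
    partner_src <- dplyr::filter(tr, .data$source == "inferred")
  }

  # dual-tagged pairs: drop observed trips of the second-tagged bird
  if ("tagged_id" %in% names(traits) && !"role" %in% names(tr)) {
    n0 <- nrow(focal)
    focal <- dplyr::semi_join(
      focal, dplyr::select(traits, "pair_id", "year", bird_id = "tagged_id"),
      by = c("pair_id", "year", "bird_id")
    )
    excl$second_tagged_bird <- n0 - nrow(focal)
  }

  miss <- dplyr::anti_join(focal, traits, by = c("pair_id", "year"))
  if (nrow(miss) > 0) {
    stop("trips with no matching traits row: ",
         paste(unique(paste0(miss$pair_id, "/", miss$year)), collapse = ", "))
  }

  excl$outside_stage_windows <- sum(focal$stage == "unassigned")
  focal <- dplyr::filter(focal, .data$stage != "unassigned")

  # partner previous-trip deviation, per pair-season, stage and partner bird
  partner_dev <- partner_src |>
    dplyr::filter(.data$stage != "unassigned") |>
    dplyr::group_by(.data$pair_id, .data$year, .data$bird_id, .data$stage) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(dev = partner_prev_deviation(
      if (dev_on == "sqrt") sqrt(.data$duration_h) else .data$duration_h
    )) |>
    dplyr::ungroup() |>
    dplyr::select("pair_id", "year", partner_bird = "bird_id", "stage",
                  partner_end = "end", "dev")

  # attach the deviation of the partner trip immediately preceding each focal trip
  key_of <- function(df) paste(df$pair_id, df$year, df$stage, sep = "\r")
  pd_split <- split(partner_dev, key_of(partner_dev))
  focal <- dplyr::bind_rows(purrr::map(split(focal, key_of(focal)), function(df) {
    df$partner_prev_dev <- NA_real_
    pd <- pd_split[[key_of(df[1, ])]]
    if (is.null(pd)) return(df)
    for (bd in unique(df$bird_id)) {
      rows <- df$bird_id == bd
      pdb <- pd[is.na(pd$partner_bird) | pd$partner_bird != bd, , drop = FALSE]
      if (nrow(pdb) == 0) next
      pdb <- pdb[order(pdb$partner_end), , drop = FALSE]
      # partner trips ending at or before the focal start count as preceding
      idx <- findInterval(as.numeric(df$start[rows]) + 1, as.numeric(pdb$partner_end))
      df$partner_prev_dev[rows] <- ifelse(idx >= 1, pdb$dev[pmax(idx, 1)], NA_real_)
    }
    df
  }))

  # covariates from the traits table, oriented to the focal bird's role
  tt <- dplyr::select(traits, dplyr::any_of(c(
    "pair_id", "year", "tagged_id", "partner_id", "tagged_sex", "partner_sex",
    "boldness_tagged", "boldness_partner", "age_tagged", "age_partner",
    "new_partner"
  )))
  focal <- dplyr::left_join(focal, tt, by = c("pair_id", "year"))
  focal_is_tagged <- if ("role" %in% names(focal)) {
    focal$role == "tagged"
  } else {
    rep(TRUE, nrow(focal))
  }
  by_role <- function(tagged_col, partner_col) {
    ifelse(focal_is_tagged, focal[[tagged_col]], focal[[partner_col]])
  }
  focal$sex <- factor(by_role("tagged_sex", "partner_sex"), levels = c("F", "M"))
  focal$focal_boldness <- by_role("boldness_tagged", "boldness_partner")
  focal$partner_boldness <- by_role("boldness_partner", "boldness_tagged")
  focal$focal_age_raw <- by_role("age_tagged", "age_partner")
  focal$partner_age_raw <- by_role("age_partner", "age_tagged")
  focal$new_partner <- as.numeric(focal$new_partner)
  focal$focal_bird <- focal$bird_id
  focal$partner_bird <- if (all(c("tagged_id", "partner_id") %in% names(focal))) {
    ifelse(focal_is_tagged, focal$partner_id, focal$tagged_id)
  } else {
    NA_character_
  }

  # response and date
  win_keys <- intersect(c("pair_id", "year"), names(windows))
  focal <- focal |>
    dplyr::left_join(dplyr::select(windows, dplyr::all_of(win_keys),
                                   "incubation_start"),
                     by = win_keys) |>
    dplyr::mutate(
      response = sqrt(.data$duration_h),
      date = as.numeric(difftime(.data$start, .data$incubation_start,
                                 units = "days"))
    )

  # row filters before scaling; the first brooding trip is flagged on the
  # original trip order (its partner-previous observation belongs to
  # incubation), independently of the deviation filter
  focal <- focal |>
    dplyr::group_by(.data$pair_id, .data$year, .data$bird_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.first_brood = drop_first_brooding &
                    .data$stage == "brooding" &
                    cumsum(.data$stage == "brooding") == 1) |>
    dplyr::ungroup()
  excl$first_brooding_trip <- sum(focal$.first_brood)
  excl$undefined_partner_deviation <-
    sum(is.na(focal$partner_prev_dev) & !focal$.first_brood)
  focal <- focal |>
    dplyr::filter(!.data$.first_brood, !is.na(.data$partner_prev_dev)) |>
    dplyr::select(-".first_brood")

  # per-stage age collapsing, counted over distinct birds (focal and partner)
  bounds <- list()
  for (st in unique(focal$stage)) {
    in_st <- focal$stage == st
    bird_age <- tibble::tibble(
      bird = c(focal$focal_bird[in_st], focal$partner_bird[in_st]),
      age = c(focal$focal_age_raw[in_st], focal$partner_age_raw[in_st])
    )
    coll <- collapse_ages(bird_age$age, bird_age$bird, min_count = min_age_count)
    lo <- attr(coll, "lower_bound"); hi <- attr(coll, "upper_bound")
    bounds[[st]] <- c(lower = lo, upper = hi)
    focal$focal_age_raw[in_st] <- pmin(pmax(focal$focal_age_raw[in_st], lo), hi)
    focal$partner_age_raw[in_st] <- pmin(pmax(focal$partner_age_raw[in_st], lo), hi)
  }

  # pooled scaling across stages, then quadratics on the scaled linear terms
  cont <- c("focal_boldness", "partner_boldness", "focal_age_raw",
            "partner_age_raw", "date", "partner_prev_dev")
  scaling <- purrr::map(setNames(cont, cont), function(cl) {
    if (scale_covariates) {
      m <- mean(focal[[cl]]); s <- sd(focal[[cl]])
      if (!is.finite(s) || s == 0) s <- 1
    } else {
      m <- 0; s <- 1
    }
    c(mean = m, sd = s)
  })
  for (cl in cont) {
    focal[[cl]] <- (focal[[cl]] - scaling[[cl]]["mean"]) / scaling[[cl]]["sd"]
  }
  focal <- focal |>
    dplyr::rename(focal_age = "focal_age_raw", partner_age = "partner_age_raw") |>
    dplyr::mutate(
      focal_age_sq = .data$focal_age^2,
      partner_age_sq = .data$partner_age^2,
      pair_id = factor(.data$pair_id),
      year = factor(.data$year)
    )

  keep <- c("response", "sex", "new_partner", "focal_boldness",
            "partner_boldness", "focal_age", "focal_age_sq", "partner_age",
            "partner_age_sq", "date", "partner_prev_dev", "pair_id", "year",
            "stage", "start", "duration_h")
  focal <- dplyr::select(focal, dplyr::all_of(keep))

  out <- list(
    incubation = dplyr::filter(focal, .data$stage == "incubation"),
    brooding = dplyr::filter(focal, .data$stage == "brooding"),
    manifest = list(
      dev_on = dev_on,
      scaled = scale_covariates,
      scaling = scaling,
      age_bounds = bounds,
      exclusions = excl,
      n_retained = nrow(focal),
      n_input_focal_trips = nrow(focal) + sum(unlist(excl))
    )
  )
  class(out) <- "trip_model_table"
  out
}

#' @export
print.trip_model_table <- function(x, ...) {
  cat("<trip_model_table> incubation:", nrow(x$incubation),
      "rows; brooding:", nrow(x$brooding), "rows\n")
  ex <- x$manifest$exclusions
  if (length(ex) > 0) {
    cat("excluded:", paste(names(ex), unlist(ex), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
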