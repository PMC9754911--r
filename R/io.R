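#' Read / write a simulator configuration file
#'
#' The configuration is stored as a flat YAML key-value file mirroring the
#' [sim_config()] fields (`beta` as a nested map), so simulation settings can
#' be versioned alongside a study.
#'
#' @param config A [sim_config()] object.
#' @param path File path (conventionally `.yml`).
#' @return `write_sim_config()`: the path, invisibly. `read_sim_config()`:
#'   a validated `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$sigma_resid <- as.list(x$sigma_resid)  # keep the stage names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sigma_resid <- unlist(raw$sigma_resid)
  cfg <- sim_config(
    n_pairs = raw$n_pairs, n_years = raw$n_years, seed = raw$seed,
    beta = raw$beta,
    sigma_pair_intercept = raw$sigma_pair_intercept,
    sigma_pair_slope = raw$sigma_pair_slope,
    sigma_year = raw$sigma_year, sigma_resid = sigma_resid,
    rho_pair = raw$rho_pair,
    overlap_lag_mean_h = raw$overlap_lag_mean_h,
    season_start_md = raw$season_start_md,
    mean_hatch_md = raw$mean_hatch_md,
    brooding_end_md = raw$brooding_end_md,
    hatch_sd_days = raw$hatch_sd_days,
    min_trip_h = raw$min_trip_h,
    trip_wet_mean_h = raw$trip_wet_mean_h,
    trip_dry_mean_h = raw$trip_dry_mean_h,
    trip_dry_max_h = raw$trip_dry_max_h,
    min_wet_bout_h = raw$min_wet_bout_h,
    logger_dialect = raw$logger_dialect,
    bin_width_min = raw$bin_width_min,
    wet_threshold_s = raw$wet_threshold_s
  )
  cfg
}

#' Write the stage model tables and their manifest
#'
#' Writes `incubation_model_table.csv`, `brooding_model_table.csv` and
#' `model_table_manifest.json` (scaling means/SDs, age-collapsing bounds and
#' the itemised exclusion counts), so a model table can be reconstructed and
#' audited outside R.
#'
#' @param model_table A [build_model_table()] result.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_model_table <- function(model_table, dir) {
  stopifnot(inherits(model_table, "trip_model_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (stage in c("incubation", "brooding")) {
    f <- file.path(dir, paste0(stage, "_model_table.csv"))
    utils::write.csv(iso_times(model_table[[stage]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  man <- model_table$manifest
  man$scaling <- lapply(man$scaling, as.list)
  man$age_bounds <- lapply(man$age_bounds, as.list)
  f_man <- file.path(dir, "model_table_manifest.json")
  jsonlite::write_json(man, f_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, f_man))
}

#' Write a model-selection result as plain-text tables
#'
#' Writes, per stage: the ranked candidate table
#' (`<stage>_model_ranking.csv`), the model-averaged estimates
#' (`<stage>_averaged_estimates.csv`, with suppressed interaction-linked
#' estimates masked as in the printed table), the random-effect standard
#' deviations of the global model (`<stage>_random_effects.csv`), and a JSON
#' manifest with the R-squared values and selection settings.
#'
#' @param selection A [select_models()] result.
#' @param dir Output directory, created if missing.
#' @param stage Stage label used as the file prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_selection <- function(selection, dir, stage = "stage") {
  stopifnot(inherits(selection, "model_selection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_rank <- file.path(dir, paste0(stage, "_model_ranking.csv"))
  utils::write.csv(selection$ranking, f_rank, row.names = FALSE)

  av <- tibble::as_tibble(selection$averaged)
  av$estimate[av$suppressed] <- NA_real_
  av$se[av$suppressed] <- NA_real_
  f_avg <- file.path(dir, paste0(stage, "_averaged_estimates.csv"))
  utils::write.csv(av, f_avg, row.names = FALSE)

  f_re <- file.path(dir, paste0(stage, "_random_effects.csv"))
  gm <- selection$global_fit$model
  re <- if (!is.null(gm)) {
    as.data.frame(lme4::VarCorr(gm))
  } else {
    data.frame()
  }
  utils::write.csv(re, f_re, row.names = FALSE)

  f_manifest <- file.path(dir, paste0(stage, "_manifest.json"))
  manifest <- list(
    stage = stage,
    n_candidates = length(selection$fits) + selection$n_dropped,
    n_dropped_nonconverged = selection$n_dropped,
    n_best_set = length(selection$best),
    n_final_set = length(selection$final),
    delta = selection$delta,
    global_terms = selection$global_terms,
    r2_marginal = unname(selection$r2_global[["marginal"]]),
    r2_conditional = unname(selection$r2_global[["conditional"]]),
    package_version = as.character(utils::packageVersion("paircoord"))
  )
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_rank, f_avg, f_re, f_manifest))
}
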