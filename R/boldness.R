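#' Score boldness from repeated human-approach assays
#'
#' Each assay records a bird's graded response to an approaching human on an
#' ordinal 0--5 scale (0 = no response, 5 = vacates the nest). Repeated
#' observations are converted into one score per bird by fitting a linear
#' model of the response on observation number (a continuous habituation
#' trend), observer identity and bird identity, with sum-to-zero contrasts so
#' per-bird effects are expressed against the population mean. The bird
#' effects, re-centred to mean zero across birds, are the boldness scores.
#'
#' @param observations Tibble with columns `bird_id`, `observer_id`,
#'   `observation_number` (integer rank of the assay within bird) and
#'   `response` (integer 0--5).
#' @return Tibble with `bird_id` and `boldness_score`; scores have mean zero
#'   over scored birds.
#' @examples
#' obs <- tibble::tibble(
#'   bird_id = c("a", "b"), observer_id = "o1",
#'   observation_number = 1L, response = c(3L, 5L)
#' )
#' score_boldness(obs)
#' @export
score_boldness <- function(observations) {
  req <- c("bird_id", "observer_id", "observation_number", "response")
  if (nrow(observations) == 0) stop("no boldness observations supplied")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(observations$response %in% 0:5)) {
    stop("response must be an integer on the 0-5 ordinal scale")
  }
  obs <- observations |>
    dplyr::mutate(bird = factor(.data$bird_id),
                  observer = factor(.data$observer_id))
  if (nlevels(obs$bird) < 2) stop("need at least two birds to score boldness")

  single_obs <- obs |>
    dplyr::group_by(.data$bird) |>
    dplyr::summarise(n_observers = dplyr::n_distinct(.data$observer),
                     .groups = "drop")
  if (nlevels(obs$observer) > 1 && any(single_obs$n_observers == 1)) {
    warning("bird(s) observed by a single observer only; their estimates are ",
            "aliased contrasts with that observer: ",
            paste(single_obs$bird[single_obs$n_observers == 1], collapse = ", "),
            call. = FALSE)
  }

  terms <- c("observation_number",
             if (nlevels(obs$observer) > 1) "observer", "bird")
  form <- stats::reformulate(terms, response = "response")
  fit <- lm(form, data = obs,
            contrasts = c(
              if (nlevels(obs$observer) > 1) list(observer = "contr.sum"),
              list(bird = "contr.sum")
            ))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0  # rank-deficient designs (e.g. constant observation number)
  bird_cf <- cf[grepl("^bird", names(cf))]
  effects <- c(bird_cf, -sum(bird_cf))  # contr.sum: last level is minus the sum
  names(effects) <- levels(obs$bird)
  scores <- effects - mean(effects)
  tibble::tibble(bird_id = names(scores), boldness_score = unname(scores))
}
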