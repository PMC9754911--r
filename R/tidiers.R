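#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted candidate mixed model
#'
#' @param x An [fit_lmm()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `se`.
#' @export
#' @importFrom generics tidy
tidy.lmm_fit <- function(x, ...) {
  if (is.null(x$coefficients)) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          se = numeric(0)))
  }
  x$coefficients
}

#' One-row summary of a fitted candidate mixed model
#'
#' @param x An [fit_lmm()] result.
#' @param ... Unused.
#' @return Tibble with `nobs`, `k`, `logLik`, `AICc`, `sigma`, `converged`,
#'   `singular`.
#' @export
#' @importFrom generics glance
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, k = x$k, logLik = x$logLik, AICc = x$aicc,
    sigma = if (!is.null(x$model)) stats::sigma(x$model) else NA_real_,
    converged = isTRUE(x$converged), singular = isTRUE(x$singular)
  )
}

#' Tidy a model-selection result
#'
#' @param x A [select_models()] result.
#' @param ... Unused.
#' @return The model-averaged coefficient table (tibble).
#' @export
tidy.model_selection <- function(x, ...) {
  tibble::as_tibble(x$averaged)
}

#' One-row summary of a model-selection result
#'
#' @param x A [select_models()] result.
#' @param ... Unused.
#' @return Tibble with candidate counts, final-set size and global-model R2.
#' @export
glance.model_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$fits) + x$n_dropped,
    n_converged = length(x$fits),
    n_best_set = length(x$best),
    n_final_set = length(x$final),
    r2_marginal = x$r2_global[["marginal"]],
    r2_conditional = x$r2_global[["conditional"]]
  )
}
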