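#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of estimated parameters, counting fixed effects, variance
#'   and covariance components, and the residual variance.
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-5, 3, 10)  # 20
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# --- term dependency rules ---------------------------------------------------
# a quadratic term "<x>_sq" requires "<x>"; an interaction "a:b" requires both
# parts; dependencies are closed transitively.
term_requirements <- function(term) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    unique(c(parts, unlist(lapply(parts, term_requirements))))
  } else if (grepl("_sq$", term)) {
    sub("_sq$", "", term)
  } else {
    character(0)
  }
}

#' Is a set of fixed-effect terms marginality-valid?
#'
#' Valid means every quadratic term is accompanied by its linear term and
#' every interaction by both of its main effects (transitively).
#'
#' @param terms Character vector of term names.
#' @return Logical scalar.
#' @export
is_marginal <- function(terms) {
  all(vapply(terms, function(tm) all(term_requirements(tm) %in% terms), TRUE))
}

#' Enumerate all marginality-valid submodels of a global model
#'
#' Generates every subset of the global fixed-effect terms that respects
#' marginality, including the intercept-only model. The random structure is
#' common to all candidates and is not part of the enumeration.
#'
#' @param global_terms Character vector of fixed-effect terms; quadratics are
#'   written `"<x>_sq"`, interactions `"a:b"`.
#' @param max_specs Guard against combinatorial explosion.
#' @return List of character vectors (term sets), the first being
#'   `character(0)`.
#' @examples
#' length(enumerate_specs(c("x", "x_sq")))       # 3
#' length(enumerate_specs(c("a", "b", "a:b")))   # 5
#' @export
enumerate_specs <- function(global_terms, max_specs = 1e5) {
  m <- length(global_terms)
  if (2^m > max_specs) {
    stop("global model implies up to ", 2^m, " subsets; raise max_specs ",
         "or reduce the global term set")
  }
  specs <- list(character(0))
  for (tm in global_terms) {
    specs <- c(specs, lapply(specs, function(s) c(s, tm)))
  }
  specs <- Filter(function(s) is_marginal(s), specs)
  specs[order(lengths(specs))]
}

#' Fit one candidate linear mixed model
#'
#' Fits the square-root trip-duration response on the candidate fixed-effect
#' terms with the study's fixed random structure: random intercepts for pair
#' and year, and a random slope of the partner previous-trip deviation by
#' pair (unstructured intercept-slope covariance; if that fit fails to
#' converge the model is refit with independent components and the fallback
#' recorded). Singular fits are retained with a flag — a near-zero
#' random-slope variance is itself a finding (little between-pair variation
#' in coordination strength) — while non-converged fits are flagged for
#' exclusion from ranking.
#'
#' @param data One stage's model table (a tibble from [build_model_table()]).
#' @param terms Character vector of fixed-effect terms (possibly empty).
#' @param method `"ML"` (comparable likelihoods across fixed structures; the
#'   default for ranking) or `"REML"` (for reported coefficients).
#' @return An object of class `"lmm_fit"`: list with `terms`, `model` (the
#'   `merMod`), `coefficients` (tibble `term`, `estimate`, `se`), `varcomp`,
#'   `logLik`, `k`, `n`, `aicc`, `converged`, `singular`, `cov_structure`.
#' @export
fit_lmm <- function(data, terms = character(0), method = c("ML", "REML")) {
  method <- match.arg(method)
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_with <- function(re) {
    f <- stats::as.formula(paste("response ~", rhs, "+", re, "+ (1 | year)"))
    warned <- FALSE
    m <- withCallingHandlers(
      tryCatch(lme4::lmer(f, data = data, REML = (method == "REML"),
                          control = ctrl),
               error = function(e) e),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    list(model = m, warned = warned)
  }
  res <- fit_with("(1 + partner_prev_dev | pair_id)")
  cov_structure <- "unstructured"
  bad <- function(r) inherits(r$model, "error") ||
    length(r$model@optinfo$conv$lme4$messages %||% character(0)) > 0
  if (bad(res)) {
    res <- fit_with("(1 + partner_prev_dev || pair_id)")
    cov_structure <- "independent"
  }
  if (inherits(res$model, "error")) {
    return(structure(list(terms = terms, model = NULL, coefficients = NULL,
                          varcomp = NULL, logLik = NA_real_, k = NA_real_,
                          n = nrow(data), aicc = NA_real_, converged = FALSE,
                          singular = NA, cov_structure = cov_structure),
                     class = "lmm_fit"))
  }
  m <- res$model
  converged <- length(m@optinfo$conv$lme4$messages %||% character(0)) == 0
  singular <- lme4::isSingular(m)
  sm <- summary(m)$coefficients
  coefs <- tibble::tibble(term = rownames(sm),
                          estimate = unname(sm[, "Estimate"]),
                          se = unname(sm[, "Std. Error"]))
  vc <- lme4::VarCorr(m)
  n_vc <- sum(vapply(vc, function(block) {
    q <- nrow(block)
    q * (q + 1) / 2
  }, numeric(1)))
  k <- nrow(sm) + n_vc + 1  # fixed effects + (co)variance components + residual
  ll <- as.numeric(stats::logLik(m))
  structure(list(
    terms = terms, model = m, coefficients = coefs,
    varcomp = vc, logLik = ll, k = k, n = nrow(data),
    aicc = aicc(ll, k, nrow(data)),
    converged = converged, singular = singular, cov_structure = cov_structure
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)",
      "\n  AICc ", round(x$aicc, 2), ", k ", x$k, ", n ", x$n,
      if (!isTRUE(x$converged)) "  [not converged]",
      if (isTRUE(x$singular)) "  [singular]", "\n", sep = "")
  invisible(x)
}

#' Extract the best-supported model set
#'
#' Models within `delta` AICc units of the minimum (strict `<`), sorted by
#' AICc.
#'
#' @param fits List of [fit_lmm()] results (or any objects with an `aicc`
#'   element).
#' @param delta AICc window.
#' @return Sorted sublist of `fits`.
#' @export
best_set <- function(fits, delta = 2) {
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  keep <- which(a - min(a, na.rm = TRUE) < delta & !is.na(a))
  fits[keep[order(a[keep])]]
}

#' Exclude nested models from a best-supported set
#'
#' A model is removed when the set contains a strictly simpler model (its
#' fixed terms a strict subset) with a lower AICc: the extra terms failed to
#' buy enough likelihood and retaining the richer model would overstate the
#' evidence for them.
#'
#' @param fits Model set as from [best_set()].
#' @return Filtered list, original order preserved.
#' @export
exclude_nested <- function(fits) {
  if (length(fits) <= 1) return(fits)
  drop <- vapply(seq_along(fits), function(i) {
    any(vapply(seq_along(fits), function(j) {
      if (i == j) return(FALSE)
      ti <- fits[[i]]$terms; tj <- fits[[j]]$terms
      all(tj %in% ti) && length(tj) < length(ti) &&
        fits[[j]]$aicc < fits[[i]]$aicc
    }, TRUE))
  }, TRUE)
  fits[!drop]
}

#' Akaike weights
#'
#' @param aicc_values Numeric AICc values.
#' @return Weights proportional to `exp(-delta/2)`, summing to 1.
#' @examples
#' round(akaike_weights(c(100, 102)), 3)  # 0.731 0.269
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-average coefficients over a best-supported set
#'
#' Computes Akaike weights over the (post-exclusion) set and averages each
#' coefficient over the models that contain it (conditional, "natural"
#' averaging; `method = "full"` instead substitutes zero where a term is
#' absent and averages over all models). Unconditional standard errors follow
#' the standard weighted combination of within-model error and between-model
#' spread, `se = sum(w_i * sqrt(se_i^2 + (b_i - b_bar)^2))`. Coefficients
#' involved in retained interactions are flagged `suppressed`: their averaged
#' main-effect estimates are not interpretable on their own and are masked in
#' the printed table.
#'
#' @param fits Model set (list of [fit_lmm()] results or stubs with `aicc`,
#'   `terms` and a `coefficients` tibble).
#' @param method `"conditional"` (default) or `"full"`.
#' @return A tibble of class `"averaged_estimates"`: `term`, `estimate`,
#'   `se`, `presence_weight`, `n_models`, `suppressed`; model weights are in
#'   the `"weights"` attribute.
#' @export
model_average <- function(fits, method = c("conditional", "full")) {
  method <- match.arg(method)
  if (length(fits) == 0) stop("empty model set")
  w <- akaike_weights(vapply(fits, function(f) f$aicc, numeric(1)))
  coef_names <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))

  # coefficient names appearing in retained interactions, plus the
  # interactions' component names, are suppressed in the primary table
  inter <- coef_names[grepl(":", coef_names, fixed = TRUE)]
  suppressed_names <- unique(c(inter, unlist(strsplit(inter, ":", fixed = TRUE))))

  rows <- purrr::map(coef_names, function(nm) {
    est <- vapply(fits, function(f) {
      i <- match(nm, f$coefficients$term)
      if (is.na(i)) NA_real_ else f$coefficients$estimate[i]
    }, numeric(1))
    ses <- vapply(fits, function(f) {
      i <- match(nm, f$coefficients$term)
      if (is.na(i)) NA_real_ else f$coefficients$se[i]
    }, numeric(1))
    has <- !is.na(est)
    if (method == "full") {
      est[!has] <- 0; ses[!has] <- 0
      wi <- w
    } else {
      wi <- w[has] / sum(w[has])
      est <- est[has]; ses <- ses[has]
    }
    b <- sum(wi * est)
    se <- sum(wi * sqrt(ses^2 + (est - b)^2))
    tibble::tibble(term = nm, estimate = b, se = se,
                   presence_weight = sum(w[has]), n_models = sum(has),
                   suppressed = nm %in% suppressed_names)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "weights") <- w
  attr(out, "method") <- method
  class(out) <- c("averaged_estimates", class(out))
  out
}

#' @export
print.averaged_estimates <- function(x, ...) {
  shown <- x
  class(shown) <- setdiff(class(shown), "averaged_estimates")
  shown$estimate[shown$suppressed] <- NA_real_
  shown$se[shown$suppressed] <- NA_real_
  print(shown, ...)
  if (any(x$suppressed)) {
    cat("# estimates of terms in retained interactions are suppressed (NA)\n")
  }
  invisible(x)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed plus
#' random effects (conditional), after Nakagawa & Schielzeth. For the random
#' slope, the pair-level contribution uses the mean-weighted formulation
#' `V_pair = v00 + 2 v01 mean(z) + v11 mean(z^2)` with `z` the slope
#' covariate.
#'
#' Called with three numerics it is the closed form on known variance
#' components: `r2_nakagawa(2, 1, 1)` gives `c(marginal = 0.5,
#' conditional = 0.75)`.
#'
#' @param object An [fit_lmm()] result, or the fixed-effect predictor
#'   variance.
#' @param random,residual Summed random-effect variance and residual variance
#'   (numeric form only).
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(object, random = NULL, residual = NULL) {
  if (is.numeric(object)) {
    stopifnot(!is.null(random), !is.null(residual))
    vf <- object; vr <- random; ve <- residual
  } else {
    stopifnot(inherits(object, "lmm_fit"), !is.null(object$model))
    m <- object$model
    vf <- var(as.numeric(model.matrix(m) %*% lme4::fixef(m)))
    vc <- lme4::VarCorr(m)
    z <- m@frame$partner_prev_dev
    vr <- 0
    for (g in names(vc)) {
      block <- vc[[g]]
      if (nrow(block) == 1) {
        vr <- vr + block[1, 1]
      } else {
        idx <- match("partner_prev_dev", rownames(block))
        vr <- vr + block["(Intercept)", "(Intercept)"] +
          2 * block["(Intercept)", idx] * mean(z) +
          block[idx, idx] * mean(z^2)
      }
    }
    ve <- attr(vc, "sc")^2
  }
  tot <- vf + vr + ve
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Variance inflation factors for a candidate fixed-effect set
#'
#' A simple collinearity diagnostic for the fixed-effect design: for each
#' non-intercept column of the model matrix, `VIF = 1 / (1 - R2)` from the
#' least-squares regression of that column on the others. Values near 1 mean
#' the covariate is nearly orthogonal to the rest; values above ~5 signal
#' that simultaneous inclusion (e.g. of focal and partner traits) could
#' destabilise coefficients.
#'
#' @param data One stage's model table.
#' @param terms Character vector of fixed-effect terms.
#' @return Tibble with `column` (model-matrix column) and `vif`.
#' @export
vif_diagnostic <- function(data, terms) {
  stopifnot(length(terms) >= 2)
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(f, data = data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
  tibble::tibble(column = colnames(X), vif = vifs)
}

#' Fit, rank, prune and average all candidate models for one stage
#'
#' The full multimodel-inference workflow: enumerate every marginality-valid
#' submodel of the global fixed-effect set, fit each by maximum likelihood
#' (so likelihoods are comparable across fixed structures), rank by AICc,
#' extract the set within `delta` AICc of the best, exclude nested models,
#' optionally refit the final set by REML for reported coefficients, and
#' model-average. Non-converged candidates are dropped from the ranking with
#' a logged count; singular-but-converged candidates are retained.
#'
#' @param data One stage's model table.
#' @param global_terms Character vector defining the global model.
#' @param delta AICc window for the best-supported set.
#' @param average `"conditional"` or `"full"` averaging.
#' @param reml_refit Refit the final set by REML for reported coefficients
#'   (weights stay ML-based)?
#' @param max_specs Passed to [enumerate_specs()].
#' @return Object of class `"model_selection"`: list with `ranking` (tibble:
#'   terms, k, logLik, AICc, delta, weight, singular, in_best_set, in_final_set),
#'   `fits`, `final` (post-exclusion fits used for averaging), `averaged`
#'   ([model_average()] output), `global_fit`, `r2_global`, `n_dropped`,
#'   `stage`.
#' @export
select_models <- function(data, global_terms, delta = 2,
                          average = c("conditional", "full"),
                          reml_refit = TRUE, max_specs = 1e5) {
  average <- match.arg(average)
  specs <- enumerate_specs(global_terms, max_specs = max_specs)
  fits <- purrr::map(specs, function(s) fit_lmm(data, s, method = "ML"))
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  n_dropped <- sum(!ok)
  fits <- fits[ok]
  if (length(fits) == 0) stop("no candidate model converged")

  a <- vapply(fits, function(f) f$aicc, numeric(1))
  best <- best_set(fits, delta = delta)
  final <- exclude_nested(best)

  key <- function(f) paste(sort(f$terms), collapse = "+")
  best_keys <- vapply(best, key, character(1))
  final_keys <- vapply(final, key, character(1))
  ranking <- tibble::tibble(
    terms = vapply(fits, function(f) {
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)"
    }, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = a,
    delta = a - min(a),
    weight = akaike_weights(a),
    singular = vapply(fits, function(f) isTRUE(f$singular), TRUE),
    in_best_set = vapply(fits, key, character(1)) %in% best_keys,
    in_final_set = vapply(fits, key, character(1)) %in% final_keys
  ) |>
    dplyr::arrange(.data$AICc)

  avg_input <- final
  if (reml_refit) {
    avg_input <- purrr::map(final, function(f) {
      rf <- fit_lmm(data, f$terms, method = "REML")
      if (!isTRUE(rf$converged)) return(f)
      rf$aicc <- f$aicc  # weights remain ML-based
      rf
    })
  }
  averaged <- model_average(avg_input, method = average)

  gfit <- fit_lmm(data, global_terms, method = "REML")
  structure(list(
    ranking = ranking, fits = fits, best = best, final = avg_input,
    averaged = averaged, global_fit = gfit,
    r2_global = if (isTRUE(gfit$converged) || !is.null(gfit$model))
      r2_nakagawa(gfit) else c(marginal = NA_real_, conditional = NA_real_),
    n_dropped = n_dropped, global_terms = global_terms, delta = delta
  ), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> ", length(x$fits), " converged candidates (",
      x$n_dropped, " dropped), final set ", length(x$final), " model(s)\n",
      sep = "")
  print(head(x$ranking, 5))
  cat("R2 (global): marginal ", round(x$r2_global[["marginal"]], 3),
      ", conditional ", round(x$r2_global[["conditional"]], 3), "\n", sep = "")
  invisible(x)
}

#' Summarise the evidence for coordination per breeding stage
#'
#' Pulls together, per stage: the model-averaged slope of the partner
#' previous-trip deviation (the coordination strength) with its unconditional
#' SE and presence weight — reported as absent, not zero, when no final model
#' contains it; the between-pair SD of the random coordination slope;
#' retained interactions involving the coordination term (evidence for
#' trait-dependent coordination); and the global-model R-squared. Per-pair
#' predicted slopes (fixed slope plus pair BLUP) are returned alongside.
#'
#' @param selections Named list of [select_models()] results, e.g.
#'   `list(incubation = ..., brooding = ...)`.
#' @return Object of class `"coordination_report"`: list with `summary` (one
#'   row per stage) and `pair_slopes`.
#' @export
coordination_report <- function(selections) {
  stopifnot(length(names(selections)) == length(selections))
  summaries <- purrr::imap(selections, function(sel, stage) {
    av <- sel$averaged
    i <- match("partner_prev_dev", av$term)
    present <- !is.na(i)
    gm <- sel$global_fit$model
    slope_sd <- NA_real_
    if (!is.null(gm)) {
      vc <- lme4::VarCorr(gm)$pair_id
      j <- match("partner_prev_dev", rownames(vc))
      if (!is.na(j)) slope_sd <- sqrt(vc[j, j])
    }
    inter <- av$term[grepl(":", av$term, fixed = TRUE) &
                       grepl("partner_prev_dev", av$term, fixed = TRUE)]
    tibble::tibble(
      stage = stage,
      coordination_present = present,
      slope = if (present) av$estimate[i] else NA_real_,
      se = if (present) av$se[i] else NA_real_,
      presence_weight = if (present) av$presence_weight[i] else 0,
      random_slope_sd = slope_sd,
      retained_dev_interactions = paste(inter, collapse = ", "),
      r2_marginal = sel$r2_global[["marginal"]],
      r2_conditional = sel$r2_global[["conditional"]]
    )
  })
  pair_slopes <- purrr::imap(selections, function(sel, stage) {
    gm <- sel$global_fit$model
    if (is.null(gm)) return(NULL)
    re <- lme4::ranef(gm)$pair_id
    if (!"partner_prev_dev" %in% names(re)) return(NULL)
    fe <- lme4::fixef(gm)
    fixed_slope <- if ("partner_prev_dev" %in% names(fe)) fe[["partner_prev_dev"]] else 0
    tibble::tibble(stage = stage, pair_id = rownames(re),
                   predicted_slope = fixed_slope + re$partner_prev_dev)
  })
  structure(list(summary = dplyr::bind_rows(summaries),
                 pair_slopes = dplyr::bind_rows(pair_slopes)),
            class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(s$stage, ": ", sep = "")
    if (s$coordination_present) {
      cat("coordination slope ", round(s$slope, 3), " (SE ", round(s$se, 3),
          ", presence weight ", round(s$presence_weight, 2), ")", sep = "")
    } else {
      cat("coordination term absent from the final model set")
    }
    cat("; between-pair slope SD ", round(s$random_slope_sd, 3), "\n", sep = "")
  }
  invisible(x)
}
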