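test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-5, 3, 10), 20)
  # large-n limit is plain AIC
  expect_equal(aicc(-100, 4, 1e9), -2 * -100 + 2 * 4, tolerance = 1e-6)
  # smallest valid sample: n = k + 2 adds the full 2k(k+1) penalty
  expect_equal(aicc(-5, 3, 5), 10 + 6 + 2 * 3 * 4)
  expect_error(aicc(-5, 3, 4), "n > k")
})

test_that("spec enumeration respects marginality", {
  expect_equal(length(enumerate_specs(c("x", "x_sq"))), 3)
  expect_equal(length(enumerate_specs(c("a", "b", "a:b"))), 5)
  expect_equal(enumerate_specs(character(0)), list(character(0)))

  # hand-counted: {a, a_sq, b, a:b} admits 8 valid subsets
  specs <- enumerate_specs(c("a", "a_sq", "b", "a:b"))
  expect_equal(length(specs), 8)
  expect_true(all(vapply(specs, is_marginal, TRUE)))
  # a quadratic interaction drags in the full closure
  expect_true(is_marginal(c("a", "a_sq", "z", "a_sq:z")))
  expect_false(is_marginal(c("a_sq:z", "a_sq", "z")))
  expect_error(enumerate_specs(letters, max_specs = 100), "subsets")
})

test_that("the best-supported set uses a strict AICc window", {
  fits <- list(stub_fit("a", 100), stub_fit("b", 101.9), stub_fit("c", 102.1))
  got <- best_set(fits)
  expect_equal(vapply(got, function(f) f$aicc, 1), c(100, 101.9))
  expect_equal(length(best_set(fits[1])), 1)
  # a tie at exactly delta = 2 is excluded
  tie <- list(stub_fit("a", 100), stub_fit("b", 102))
  expect_equal(length(best_set(tie)), 1)
})

test_that("nested-model exclusion matches the hand-worked sets", {
  a <- stub_fit("x", 100); b <- stub_fit(c("x", "z"), 101)
  expect_equal(exclude_nested(list(a, b)), list(a))

  a2 <- stub_fit("x", 101); b2 <- stub_fit(c("x", "z"), 100)
  expect_equal(length(exclude_nested(list(a2, b2))), 2)

  chain <- list(stub_fit(character(0), 100), stub_fit("x", 100.5),
                stub_fit(c("x", "z"), 101))
  kept <- exclude_nested(chain)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$terms, character(0))
})

test_that("nested exclusion agrees with a brute-force scan on random sets", {
  set.seed(55)
  pool <- c("a", "b", "c", "d")
  for (rep in 1:40) {
    fits <- lapply(1:6, function(i) {
      stub_fit(sample(pool, sample(0:4, 1)), stats::runif(1, 100, 104))
    })
    got <- exclude_nested(best_set(fits, delta = 4))
    # independent scan: keep i unless some j is a strict sub-model with
    # smaller AICc
    bs <- best_set(fits, delta = 4)
    keep <- rep(TRUE, length(bs))
    for (i in seq_along(bs)) {
      for (j in seq_along(bs)) {
        strict_sub <- length(setdiff(bs[[j]]$terms, bs[[i]]$terms)) == 0 &&
          length(bs[[j]]$terms) < length(bs[[i]]$terms)
        if (strict_sub && bs[[j]]$aicc < bs[[i]]$aicc) keep[i] <- FALSE
      }
    }
    expect_equal(vapply(got, function(f) f$aicc, 1),
                 vapply(bs[keep], function(f) f$aicc, 1))
  }
})

test_that("Akaike weights and averaging match the defining formulas", {
  expect_equal(round(akaike_weights(c(100, 102)), 3), c(0.731, 0.269))
  expect_equal(sum(akaike_weights(stats::runif(7, 50, 60))), 1)

  # single model: averaging is the identity
  one <- stub_fit(c("x"), 100, estimates = c(`(Intercept)` = 2, x = 0.7),
                  ses = c(`(Intercept)` = 0.2, x = 0.1))
  av <- model_average(list(one))
  expect_equal(av$estimate[av$term == "x"], 0.7)
  expect_equal(av$se[av$term == "x"], 0.1)
  expect_equal(attr(av, "weights"), 1)

  # a term with identical estimates everywhere averages to that estimate
  f1 <- stub_fit("x", 100, estimates = c(x = 0.5), ses = c(x = 0.2))
  f2 <- stub_fit(c("x", "z"), 101, estimates = c(x = 0.5, z = 1),
                 ses = c(x = 0.3, z = 0.4))
  av2 <- model_average(list(f1, f2))
  expect_equal(av2$estimate[av2$term == "x"], 0.5)
  expect_equal(av2$presence_weight[av2$term == "x"], 1)
  expect_equal(av2$presence_weight[av2$term == "z"],
               akaike_weights(c(100, 101))[2])
})

test_that("conditional averaging agrees with an independent computation", {
  set.seed(66)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    fits <- lapply(1:k, function(i) {
      terms <- sample(c("x", "z", "w"), sample(1:3, 1))
      est <- stats::rnorm(length(terms)); names(est) <- terms
      ses <- stats::runif(length(terms), 0.1, 1); names(ses) <- terms
      stub_fit(terms, stats::runif(1, 200, 204), est, ses)
    })
    av <- model_average(fits)
    w <- akaike_weights(vapply(fits, function(f) f$aicc, 1))
    for (tm in av$term) {
      has <- vapply(fits, function(f) tm %in% f$coefficients$term, TRUE)
      wi <- w[has] / sum(w[has])
      b <- vapply(fits[has], function(f) {
        f$coefficients$estimate[f$coefficients$term == tm]
      }, 1)
      s <- vapply(fits[has], function(f) {
        f$coefficients$se[f$coefficients$term == tm]
      }, 1)
      bbar <- sum(wi * b)
      expect_equal(av$estimate[av$term == tm], bbar)
      expect_equal(av$se[av$term == tm], sum(wi * sqrt(s^2 + (b - bbar)^2)))
      expect_equal(av$presence_weight[av$term == tm], sum(w[has]))
    }
  }
})

test_that("full-model averaging shrinks absent terms toward zero", {
  f1 <- stub_fit("x", 100, estimates = c(x = 1), ses = c(x = 0.1))
  f0 <- stub_fit(character(0), 100,
                 estimates = c(`(Intercept)` = 5),
                 ses = c(`(Intercept)` = 1))
  cond <- model_average(list(f1, f0), method = "conditional")
  full <- model_average(list(f1, f0), method = "full")
  expect_equal(cond$estimate[cond$term == "x"], 1)
  expect_equal(full$estimate[full$term == "x"], 0.5)
})

test_that("terms inside retained interactions are flagged and masked", {
  f <- stub_fit(c("x", "z", "x:z"), 100,
                estimates = c(x = 1, z = 2, `x:z` = 0.5, w = 3),
                ses = c(x = .1, z = .1, `x:z` = .1, w = .1))
  av <- model_average(list(f))
  expect_true(all(av$suppressed[av$term %in% c("x", "z", "x:z")]))
  expect_false(av$suppressed[av$term == "w"])
  out <- capture.output(print(av))
  expect_true(any(grepl("suppressed", out)))
  # the masked table shows NA where estimates are suppressed
  expect_match(paste(out, collapse = "\n"), "NA")
})

test_that("R-squared decomposition matches the closed form", {
  expect_equal(r2_nakagawa(2, 1, 1),
               c(marginal = 0.5, conditional = 0.75))
  expect_equal(r2_nakagawa(0, 1, 3)[["marginal"]], 0)
  expect_equal(r2_nakagawa(1, 0, 0), c(marginal = 1, conditional = 1))
})

test_that("candidate fits are deterministic with honest bookkeeping", {
  set.seed(7)
  n <- 500
  d <- tibble::tibble(
    response = stats::rnorm(n, 10, 2),
    partner_prev_dev = stats::rnorm(n),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    pair_id = factor(rep(1:50, each = 10)),
    year = factor(rep(1:5, 100))
  )
  f1 <- fit_lmm(d, character(0))
  f2 <- fit_lmm(d, character(0))
  expect_equal(f1$aicc, f2$aicc)
  # k = fixed effects + pair (2 var + 1 cov) + year + residual
  expect_equal(f1$k, 1 + 3 + 1 + 1)
  f3 <- fit_lmm(d, c("sex", "partner_prev_dev"))
  expect_equal(f3$k, 3 + 3 + 1 + 1)

  # data generated with zero random variance: residual variance is
  # recovered and the random components collapse toward zero
  expect_equal(stats::sigma(f1$model), 2, tolerance = 0.1)
  vc <- as.data.frame(lme4::VarCorr(f1$model))
  expect_lt(max(vc$vcov[vc$grp != "Residual"]), 0.3)
  r2 <- r2_nakagawa(f3)
  expect_true(r2[["marginal"]] >= 0 && r2[["marginal"]] <= r2[["conditional"]]
              && r2[["conditional"]] <= 1)
})

test_that("the generative coordination slope is recovered by the fit", {
  cfg <- sim_config(n_pairs = 30, seed = 61,
                    beta = list(coord = 0.2), sigma_pair_slope = 0.05)
  st <- simulate_study(cfg)
  mt <- build_model_table(st$trips, st$traits, true_windows(st),
                          focal_roles = c("tagged", "partner"),
                          dev_on = "sqrt", scale_covariates = FALSE)
  f <- fit_lmm(mt$incubation, "partner_prev_dev")
  est <- f$coefficients
  i <- match("partner_prev_dev", est$term)
  expect_lt(abs(est$estimate[i] - 0.2), 3 * est$se[i])
})

test_that("stronger generative coordination yields steeper recovered slopes", {
  slope_at <- function(beta, seed) {
    cfg <- sim_config(n_pairs = 25, seed = seed, beta = list(coord = beta),
                      sigma_pair_slope = 0.05)
    st <- simulate_study(cfg)
    mt <- build_model_table(st$trips, st$traits, true_windows(st),
                            focal_roles = c("tagged", "partner"),
                            dev_on = "sqrt", scale_covariates = FALSE)
    f <- fit_lmm(mt$incubation, "partner_prev_dev")
    f$coefficients$estimate[f$coefficients$term == "partner_prev_dev"]
  }
  lo <- vapply(1:6, function(s) slope_at(0, 100 + s), 1)
  hi <- vapply(1:6, function(s) slope_at(0.6, 200 + s), 1)
  expect_gt(mean(hi), mean(lo))
  expect_gt(mean(hi) - mean(lo), 0.3)
})

test_that("the selection workflow ranks, prunes and reports coherently", {
  cfg <- sim_config(n_pairs = 30, seed = 71,
                    beta = list(sex_male = -2, coord = 0.3))
  st <- simulate_study(cfg)
  mt <- build_model_table(st$trips, st$traits, true_windows(st),
                          focal_roles = c("tagged", "partner"))
  sel <- select_models(mt$incubation,
                       c("sex", "focal_boldness", "partner_prev_dev"))
  expect_s3_class(sel, "model_selection")
  expect_equal(sum(sel$ranking$weight), 1)
  expect_true(all(diff(sel$ranking$AICc) >= 0))
  expect_true(all(sel$ranking$in_final_set <= sel$ranking$in_best_set))
  expect_gt(length(sel$final), 0)
  # the strong sex effect must be selected
  expect_true(any(grepl("sex", sel$ranking$terms[sel$ranking$in_final_set])))

  g <- glance(sel)
  expect_equal(g$n_candidates, 8)
  expect_true(g$r2_marginal <= g$r2_conditional)
  td <- tidy(sel)
  expect_true(all(c("term", "estimate", "se") %in% names(td)))

  rep <- coordination_report(list(incubation = sel))
  expect_equal(nrow(rep$summary), 1)
  if (rep$summary$coordination_present) {
    expect_true(is.finite(rep$summary$slope))
  }
  expect_true(is.finite(rep$summary$random_slope_sd))

  # without the coordination term in the global set the report says absent
  sel0 <- select_models(mt$incubation, "sex")
  rep0 <- coordination_report(list(incubation = sel0))
  expect_false(rep0$summary$coordination_present)
  expect_true(is.na(rep0$summary$slope))
})
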