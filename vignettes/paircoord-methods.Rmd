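---
title: "From immersion loggers to coordination of biparental care: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From immersion loggers to coordination of biparental care: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircoord)
library(dplyr)
```

## The problem

In seabirds with obligate biparental care, one parent always attends the egg
or small chick while the other forages at sea, so parental effort is divided
into alternating foraging trips and nest shifts. Pairs are said to
*coordinate* care when the duration of a bird's foraging trip tracks its
partner's previous trip: a long partner absence answered with a long trip of
one's own keeps nest-attendance costs balanced. `paircoord` implements the
full analysis chain for studying this in wandering albatrosses (and
structurally similar central-place foragers) instrumented with leg-mounted
saltwater immersion loggers:

1. parse raw logger streams into wet/dry bouts (`parse_binned()`,
   `parse_state_change()`),
2. segment bouts into foraging trips and nest shifts
   (`extract_trips_and_shifts()`),
3. infer the untagged partner's trips from the tagged bird's attendance
   (`infer_partner_trips()`), with accuracy and nest-overlap diagnostics,
4. assign breeding stages with per-pair hatch-date detection
   (`build_stage_windows()`, `assign_stages()`),
5. score boldness from repeated human-approach assays (`score_boldness()`),
6. build the stage-specific model tables with the coordination covariate
   (`build_model_table()`),
7. fit and compare linear mixed models by AICc, exclude nested models, and
   model-average (`select_models()`, `coordination_report()`).

A paired-schedule simulator (`sim_config()`, `simulate_study()`,
`render_logger_stream()`) generates data with known trait effects and
coordination slopes so each stage can be validated against ground truth.

## Segmentation rules

Immersion loggers record either the number of seconds wet per 10-minute bin,
or the timestamp of each wet/dry transition. A bin is *wet* when its wet
seconds strictly exceed 45 s; adjacent same-state bins merge into bouts.
Bins are half-open UTC intervals (inclusive start), and all timestamps are
handled in UTC.

The species' maximum continuous flight time is about 12 h, so a dry bout
strictly longer than 12 h means the bird was on land (a *nest shift*); a dry
bout of exactly 12 h is still classified as flight — both thresholds are
deliberate strict inequalities. A *foraging trip* runs from the first wet
bout after a shift to the start of the next shift; dry bouts of 12 h or less
inside the trip are flight. Spans at the deployment edges that are not
bounded by shifts on both sides are dropped rather than clipped, because
their durations would be censored.

Because exactly one parent is at sea at any time (apart from brief
nest-relief overlaps), the partner's trips are inferred as the tagged bird's
land periods between trips. `inference_accuracy()` scores inferred against
true trips as `100 (1 - |inferred - true| / true)` percent, floored at zero;
`nest_overlap()` measures the relief delay (the nest-bound bird's departure
minus the returning bird's arrival, floored at zero) in dual-tagged pairs,
both in hours and as a percentage of the stage's mean trip duration.

## Breeding phenology

Incubation is anchored at 16 December (the earliest lay date); brooding ends
11 April; the colony mean hatch date is 15 March. Within a configurable
search window (default 1 February–11 April) `detect_hatch()` places a single
change-point on log trip duration by an exhaustive least-squares binary
split, and accepts it only when the post-split mean duration is below
`ratio_threshold` (default 0.6) times the pre-split mean; the hatch date is
then the start of the first post-split trip, and otherwise the colony mean
is used as a fallback, with the source recorded per pair. The search window,
the ratio and the minimum number of trips (4) are all arguments, and results
should be reported together with the ratio used. Stage membership of a trip
is decided by its start time; trips starting after the end of brooding are
excluded downstream.

A known limitation: localisation of the change-point degrades as
trip-duration noise approaches the size of the incubation-to-brooding drop.
Under the field-calibrated variances the generator reproduces (see below),
trip-to-trip spread within incubation is comparable to the stage contrast on
the log scale, and no split statistic can place the change-point reliably to
within one trip; the test suite measures this rate directly at study
conditions, and separately verifies near-perfect localisation when the drop
dominates the noise (residual SDs of 1.0/0.5 sqrt-hours). The
detected-versus-fallback split is always reported per pair, so downstream
results can be conditioned on how each hatch date was obtained.

## Boldness scores

Repeated responses of incubating birds to an approaching human are graded 0
(no response) to 5 (vacates the nest). `score_boldness()` fits a Gaussian
linear model of the response on observation number (continuous habituation
trend), observer identity and bird identity, with sum-to-zero contrasts so
the per-bird effects are expressed against the population mean; re-centred
bird effects are the scores. The Gaussian-identity choice treats the ordinal
score as continuous — consistent with its downstream use as a continuous
covariate — and observation number is linear rather than categorical; both
choices are open questions the interface leaves visible. A bird observed by
a single observer (when several observers exist) yields an aliased contrast
and is flagged with a warning.

## The coordination covariate and the model table

For each partner trip in a stage, the deviation is that trip's duration
minus the expanding mean of the partner's *earlier* trips in the same stage
(`partner_prev_deviation()`); the focal trip that follows receives this
deviation. The expanding mean (rather than the whole-stage mean) follows
from the word "previous": only information available at the focal bird's
decision time is used. The first partner trip of a stage has no earlier
trips, so its deviation is undefined and the dependent focal rows are
dropped (with counts itemised in the manifest); each pair's first brooding
trip is likewise dropped because its partner-previous observation belongs to
incubation.

`build_model_table()` applies, in order: stage assignment; deviation
attachment; the row filters above; per-stage collapsing of extreme ages
inward until the boundary categories hold at least five distinct birds
(guarding against spurious quadratic age effects); pooled scaling of the
continuous covariates to mean 0, SD 1 across both stages (so coefficients
are comparable between stages); then quadratic age terms as squares of the
scaled linear terms. Collapsing before scaling reconciles the two
requirements — collapse per stage subset, scale before the stage split — in
the only order that satisfies both. Binary covariates (sex, new
partnership) are factors/0-1 and are not scaled.

The response is the square root of trip duration in hours, correcting the
strong positive skew of trip durations.

`write_model_table()` exports the two stage tables with a JSON manifest of
the scaling constants, collapsing bounds and exclusion counts, so the table
construction is auditable; `write_selection()` does the same for a fitted
selection (ranked models, masked averaged estimates, random-effect SDs).

Two parameterisations of the deviation are available: `dev_on = "hours"`
(the analysis default: deviation in hours, then scaled) and `dev_on =
"sqrt"` with `scale_covariates = FALSE`, which matches the generator's
parameterisation exactly and makes parameter recovery an identity test —
the fitted slope estimates the generative slope itself.

## Mixed models and multimodel inference

Each stage is analysed separately. Every candidate model shares the random
structure: random intercepts for pair and year, and a random slope of the
partner previous-trip deviation by pair (unstructured intercept–slope
covariance; on non-convergence the model is refit with independent
components and the fallback recorded). Fixed-effect candidates are all
marginality-valid subsets of the global set (`enumerate_specs()`): a
quadratic requires its linear term, an interaction its main effects.

Ranking uses maximum likelihood, not REML, because likelihoods must be
comparable across fixed-effect structures; the final set is refit by REML
for reported coefficients while the Akaike weights remain ML-based. The
criterion is AICc with `k` counting fixed effects, variance and covariance
components, and the residual variance — documented so the ranking is
reproducible. The best-supported set is `delta AICc < 2` (strict), nested
models (supersets of a lower-AICc model in the set) are excluded, and
coefficients are model-averaged conditionally ("natural" averaging over the
models containing each term), with unconditional standard errors combining
within-model error and between-model spread. Full-model (zero-substitution)
averaging is available via `method = "full"`. Averaged coefficients of
retained interactions and their component main effects are flagged and
masked in the printed table, since a main effect averaged across models
with and without its interaction is not interpretable on its own.

Because focal and partner traits enter the same model, `vif_diagnostic()`
provides a quick collinearity check of any candidate fixed-effect set
(variance inflation from the model-matrix columns); assortative pairing by
age or boldness would show up there before it destabilises coefficients.

Singular fits (typically a near-zero random-slope variance) are retained
with a flag — low between-pair variation in coordination strength is itself
a finding — while non-converged fits are dropped from the ranking with a
logged count. `r2_nakagawa()` reports marginal and conditional R²; the
random-slope contribution uses the mean-weighted form
`v00 + 2 v01 mean(z) + v11 mean(z²)`.

## The synthetic generator

`simulate_pair_season()` builds each pair's alternating schedule
sequentially: each new trip's sqrt-duration is the stage intercept plus
trait effects, plus the coordination response `(beta_coord + pair slope) *
deviation` — the deviation computed with exactly the expanding-window rule
the analysis uses, on the sqrt scale — plus pair, year and residual
effects; squared and floored at 2 h (no biological minimum at-sea time
beyond the 12-h rule exists; the floor keeps durations positive without
affecting realistic draws). Reliefs are separated by an
exponential overlap lag, mean 1.883 h (1 h 53 min, the observed average
overlap). All fixed effects are sqrt-hours per SD of the covariate: ages
are standardised internally against the colony age distribution (mean
21.14, SD 7.67 years, range 7–42), boldness scores are centred with SD near
1, and date is standardised against the season midpoint.

Defaults are anchored to the study system: stage intercepts 11.6 and 8.05
sqrt-hours reproduce mean trip durations of 5.6 d (incubation) and 2.7 d
(brooding); stage-specific residual SDs of 4.3 and 1.7 sqrt-hours reproduce
the observed stage spreads (4.28 d and 1.36 d raw-scale SD) after adding the
pair (1.0) and year (0.5) components, via Var(sqrt X) ≈ Var(X) / (4 E X);
the default coordination slope is 0.19. Hatch dates are jittered around 15
March with SD 4 days — the colony is highly synchronous, with hatching
concentrated in mid-March.

Within a trip, rendering alternates on-water (wet) and flight (dry) bouts
with exponential lengths (means 3 h and 2 h); flight bouts are truncated at
11 h so no at-sea dry spell can masquerade as a return to land; trips start
and end with a wet bout (departure and final approach contact). Wet bouts
have a 0.2-h floor so every bout registers above the binned dialect's 45-s
threshold: the two dialects then describe the same trip set by
construction, and sub-resolution spray contacts — which the threshold
exists to ignore — are simply not modelled. On-land periods are fully dry.
Both dialects are rendered from the same wet-interval realisation; the
binned dialect aggregates true wet seconds per 10-min bin.

What the generator does *not* emulate: spatial movement, prey capture, mass
dynamics and desertion, weather-driven correlation between pair members,
logger failure or drop-out, and non-Gaussian residuals (the residual is
Gaussian on the sqrt scale by assumption; the real duration distribution's
family is unknown beyond its moments). Passing tests on simulated data
therefore validate the pipeline's correctness and calibration under the
stated generative model, not the field realism of every assumption.

## Validation problem sizes

The test suite validates: the segmentation against a brute-force bout scan
on 1,000 random sequences; dialect equivalence on six simulated birds;
partner-trip inference exactness at zero lag and monotone degradation over
a four-point lag sweep; unbiasedness and interval calibration of the
coordination slope over 200 replicates of 70 pairs at generative slopes 0,
0.2 and 0.5; term recovery of model selection over 100 replicates of 70
pairs with four generative and two null terms; hatch localisation at study
conditions over 200 series (and, separately, in the high-signal regime);
and exact closed forms for AICc, Akaike weights, R² and nested exclusion.
These sizes were chosen so each property is measured with useful precision
while the whole suite stays convenient to run routinely.

## A worked desk example

```{r example}
cfg <- sim_config(n_pairs = 12, seed = 42)
study <- simulate_study(cfg)
study

windows <- build_stage_windows(study$trips)
count(windows, hatch_source)

mt <- build_model_table(study$trips, study$traits, windows,
                        focal_roles = c("tagged", "partner"),
                        dev_on = "sqrt", scale_covariates = FALSE)
mt

sel <- select_models(mt$incubation, c("sex", "partner_boldness",
                                      "partner_prev_dev"))
sel
coordination_report(list(incubation = sel))
```
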