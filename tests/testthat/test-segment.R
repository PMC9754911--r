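bin_stream <- function(wet_seconds, bird_id = "b1", t0 = T0) {
  tibble::tibble(bird_id = bird_id,
                 bin_start_iso8601_utc = t0 + 600 * (seq_along(wet_seconds) - 1),
                 wet_seconds = wet_seconds)
}

test_that("binned parsing merges bins into alternating bouts", {
  b <- parse_binned(bin_stream(c(0, 0, 600, 600, 0)))
  expect_equal(b$state, c("dry", "wet", "dry"))
  expect_equal(b$duration_h, c(20, 20, 10) / 60)
  expect_equal(as.numeric(b$end[3] - b$start[1], units = "hours"), 50 / 60)

  # the wet threshold is a strict inequality at 45 s
  b45 <- parse_binned(bin_stream(c(600, 45, 600)))
  expect_equal(b45$state, c("wet", "dry", "wet"))
  b46 <- parse_binned(bin_stream(c(600, 46, 600)))
  expect_equal(b46$state, "wet")
  expect_equal(b46$duration_h, 0.5)

  all_dry <- parse_binned(bin_stream(rep(0, 17)))
  expect_equal(nrow(all_dry), 1)
  expect_equal(all_dry$duration_h, 17 / 6)
})

test_that("binned parsing rejects gaps, duplicates and impossible values", {
  s <- bin_stream(rep(0, 5))
  expect_error(parse_binned(s[-3, ]), "gap in bins at 2011-01-01T00:20:00Z")
  expect_error(parse_binned(rbind(s, s[2, ])), "duplicate")
  s$wet_seconds[2] <- 601
  expect_error(parse_binned(s), "wet_seconds")
})

test_that("state-change parsing builds bouts between transitions", {
  s <- tibble::tibble(
    bird_id = "b1",
    timestamp_iso8601_utc = T0 + 3600 * c(0, 5, 8),
    new_state = c("dry", "wet", "dry")
  )
  b <- parse_state_change(s, deployment_end = T0 + 3600 * 20)
  expect_equal(b$state, c("dry", "wet", "dry"))
  expect_equal(b$duration_h, c(5, 3, 12))

  # single transition: one open bout clipped to the deployment window
  one <- parse_state_change(s[2, ], deployment_end = T0 + 3600 * 7)
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_h, 2)

  # a repeated state is a logger glitch: merged, bout count as hand-merged
  glitch <- tibble::tibble(
    bird_id = "b1",
    timestamp_iso8601_utc = T0 + 3600 * c(0, 5, 6, 8),
    new_state = c("dry", "wet", "wet", "dry")
  )
  expect_warning(bg <- parse_state_change(glitch, deployment_end = T0 + 3600 * 9),
                 "repeated state")
  expect_equal(bg$state, c("dry", "wet", "dry"))
  expect_equal(bg$duration_h, c(5, 3, 1))
})

test_that("trips run from first wet bout after a shift to the next shift", {
  b <- make_bouts(c(13, 2, 1, 3, 14), first_state = "dry")
  res <- extract_trips_and_shifts(b)
  expect_equal(nrow(res$trips), 1)
  expect_equal(res$trips$duration_h, 6)  # wet 2 + flight 1 + wet 3
  expect_equal(res$trips$start, b$start[2])
  expect_equal(res$shifts$duration_h, c(13, 14))

  # an unbroken 30-h wet bout is one trip
  b2 <- make_bouts(c(13, 30, 14), first_state = "dry")
  expect_equal(extract_trips_and_shifts(b2)$trips$duration_h, 30)

  # a dry bout of exactly 12 h is flight, not a shift (strict >)
  b3 <- make_bouts(c(13, 2, 12, 3, 14), first_state = "dry")
  res3 <- extract_trips_and_shifts(b3)
  expect_equal(nrow(res3$trips), 1)
  expect_equal(res3$trips$duration_h, 17)
  expect_equal(nrow(res3$shifts), 2)
})

test_that("records without land periods yield no trips, with a warning", {
  b <- make_bouts(c(2, 3, 2, 5), first_state = "wet")
  expect_warning(res <- extract_trips_and_shifts(b), "no trips")
  expect_equal(nrow(res$trips), 0)
  expect_equal(nrow(res$shifts), 0)
})

test_that("streaming extraction equals the brute-force bout scan", {
  set.seed(101)
  for (i in 1:150) {
    b <- random_bouts()
    expected <- bf_trips_shifts(b)
    got <- suppressWarnings(extract_trips_and_shifts(b))
    expect_equal(nrow(got$trips), nrow(expected$trips))
    expect_equal(as.numeric(got$trips$start), as.numeric(expected$trips$start))
    expect_equal(got$trips$duration_h, expected$trips$duration_h)
    expect_equal(got$shifts$duration_h, expected$shifts$duration_h)
  }
})

test_that("trips and shifts tile the record between the outermost shifts", {
  set.seed(77)
  for (i in 1:25) {
    b <- random_bouts(30)
    res <- suppressWarnings(extract_trips_and_shifts(b))
    if (nrow(res$shifts) < 2 || nrow(res$trips) == 0) next
    pieces <- rbind(
      data.frame(start = as.numeric(res$trips$start),
                 end = as.numeric(res$trips$end)),
      data.frame(start = as.numeric(res$shifts$start),
                 end = as.numeric(res$shifts$end))
    )
    pieces <- pieces[order(pieces$start), ]
    # each trip starts exactly where the preceding shift ends, and ends
    # exactly where the next shift starts: no gaps, no overlaps
    expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)])
  }
})

test_that("partner trips are inferred from gaps between observed trips", {
  tr <- tibble::tibble(
    bird_id = "b1",
    start = T0 + 3600 * c(0, 250),
    end = T0 + 3600 * c(100, 330)
  )
  inf <- infer_partner_trips(tr, partner_id = "mate")
  expect_equal(nrow(inf), 1)
  expect_equal(inf$duration_h, 150)
  expect_equal(inf$source, "inferred")
  expect_equal(inf$bird_id, "mate")
  expect_equal(nrow(infer_partner_trips(tr[1, ])), 0)
})

test_that("zero-lag inference is exact; accuracy follows its definition", {
  st <- simulate_study(quiet_config(n_pairs = 3, seed = 13))
  for (p in unique(st$trips$pair_id)) {
    tagged <- st$trips[st$trips$pair_id == p & st$trips$role == "tagged", ]
    truth <- st$trips[st$trips$pair_id == p & st$trips$role == "partner", ]
    inf <- infer_partner_trips(tagged, partner_id = truth$bird_id[1])
    acc <- inference_accuracy(inf, truth)
    expect_equal(acc$mean_accuracy_pct, 100, tolerance = 1e-9)
  }
  # the stated formula: true 100 h, inferred 110 h -> 90 %
  tru <- tibble::tibble(bird_id = "m", start = T0, end = T0 + 100 * 3600,
                        duration_h = 100)
  inf <- tibble::tibble(bird_id = "m", start = T0 - 5 * 3600,
                        end = T0 + 105 * 3600, duration_h = 110)
  expect_equal(inference_accuracy(inf, tru)$mean_accuracy_pct, 90)
  # and it is floored at zero, never negative
  inf$duration_h <- 500
  expect_equal(inference_accuracy(inf, tru)$mean_accuracy_pct, 0)
})

test_that("nest overlap averages relief delays and scales by stage means", {
  # hand-built alternating schedule with a fixed 2-h relief delay
  starts <- c(0, 102, 204, 306)
  tr <- tibble::tibble(
    bird_id = rep(c("a", "b"), 2),
    start = T0 + 3600 * starts,
    end = T0 + 3600 * (starts + 100),
    duration_h = 100,
    stage = "incubation"
  )
  ov <- nest_overlap(tr)
  expect_equal(ov$mean_overlap_h, 2)
  expect_equal(ov$pct_of_mean_trip, 100 * 2 / 100)
  expect_equal(ov$n_events, 3)

  # zero-lag simulated pair: overlap is identically zero
  st <- simulate_study(quiet_config(n_pairs = 1, seed = 4))
  ov0 <- nest_overlap(st$trips)
  expect_true(all(abs(ov0$mean_overlap_h) < 1e-9))

  # several pairs passed together: relief events never cross pair boundaries
  tr2 <- tr
  tr2$pair_id <- "P2"
  tr2$start <- tr2$start + 3600 * 51  # interleave with the first pair
  tr2$end <- tr2$end + 3600 * 51
  tr$pair_id <- "P1"
  both <- rbind(tr, tr2)
  ov2 <- nest_overlap(both)
  expect_equal(ov2$mean_overlap_h, 2)
  expect_equal(ov2$n_events, 6)
})
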