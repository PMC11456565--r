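test_that("flight track follows the plan's heading geometry", {
  plan <- flight_plan(heading = c(127, 40), altitude = c(1800, 3000),
                      speed = 75, duration = 60)
  track <- generate_flight_track(plan, seed = 1, heading_jitter = 0,
                                 altitude_jitter = 0, speed_jitter = 0)
  # total circular change across the turn equals the published delta
  step <- turnload:::signed_heading_step(head(track$heading_deg, -1),
                                         track$heading_deg[-1])
  expect_equal(abs(sum(step)), 87, tolerance = 1e-8)
  # altitude climbs 1800 -> 3000 during the turn
  expect_equal(track$altitude_ft[1], 1800)
  expect_equal(track$altitude_ft[nrow(track)], 3000)
})

test_that("single-leg plan yields constant heading and no turns", {
  plan <- flight_plan(heading = 90, altitude = 2000, speed = 80,
                      duration = 400)
  track <- generate_flight_track(plan, seed = 2)
  expect_lt(diff(range(track$heading_deg)), 3)   # jitter only
  expect_equal(nrow(detect_turns(track)), 0)
  expect_equal(nrow(true_turn_segments(plan)), 0)
})

test_that("generators are deterministic in the seed", {
  plan <- default_flight_plan(leg_duration = 30)
  t1 <- generate_flight_track(plan, seed = 11)
  t2 <- generate_flight_track(plan, seed = 11)
  expect_identical(t1, t2)
  segs <- true_turn_segments(plan)
  r1 <- generate_rr_series(t1, segs, seed = 5)
  r2 <- generate_rr_series(t2, segs, seed = 5)
  expect_identical(r1, r2)
  d1 <- make_dataset(2, plan, seed = 3)
  d2 <- make_dataset(2, plan, seed = 3)
  expect_identical(d1, d2)
  expect_equal(nrow(make_dataset(4, plan, seed = 3)), 4)
})

test_that("empty plan is rejected", {
  expect_error(flight_plan(numeric(), numeric(), numeric(), numeric()),
               "empty flight plan")
  expect_error(generate_flight_track(NULL), "empty flight plan")
})

test_that("zero modulation and noise give exactly constant intervals", {
  plan <- flight_plan(heading = 10, altitude = 1000, speed = 70,
                      duration = 120)
  track <- generate_flight_track(plan, seed = 1)
  params <- load_class_params(class_id = 0:3, base_hr = 60,
                              lf_amp = 0, hf_amp = 0)
  rr <- generate_rr_series(track, true_turn_segments(plan), params, seed = 1)
  expect_true(all(rr$rr_ms == 1000))
})

test_that("mean RR tracks the configured heart rate", {
  plan <- flight_plan(heading = 10, altitude = 1000, speed = 70,
                      duration = 60)
  track <- generate_flight_track(plan, seed = 1)
  params <- load_class_params(class_id = 0:3, base_hr = 90,
                              lf_amp = 0, hf_amp = 0)
  rr <- generate_rr_series(track, true_turn_segments(plan), params, seed = 1)
  expect_equal(mean(rr$rr_ms), 60000 / 90, tolerance = 1 / (60000 / 90))
})

test_that("rate fidelity holds within 1% under zero modulation", {
  plan <- flight_plan(heading = 10, altitude = 1000, speed = 70,
                      duration = 300)
  track <- generate_flight_track(plan, seed = 4)
  for (hr in c(55, 75, 110)) {
    params <- load_class_params(class_id = 0:3, base_hr = hr,
                                lf_amp = 0, hf_amp = 0)
    rr <- generate_rr_series(track, true_turn_segments(plan), params,
                             seed = 4)
    expect_equal(mean(60000 / rr$rr_ms), hr, tolerance = 0.01)
  }
})

test_that("raising hf_amp raises expected rmssd monotonically", {
  plan <- flight_plan(heading = 10, altitude = 1000, speed = 70,
                      duration = 180)
  track <- generate_flight_track(plan, seed = 1)
  segs <- true_turn_segments(plan)
  mean_rmssd <- function(hf) {
    vals <- vapply(1:20, function(s) {
      params <- load_class_params(class_id = 0:3, base_hr = 80, lf_amp = 20,
                                  hf_amp = hf, noise_sd = 5)
      rr <- generate_rr_series(track, segs, params, seed = s)
      mean(extract_features(rr)$rmssd)
    }, numeric(1))
    mean(vals)
  }
  r <- vapply(c(10, 30, 60), mean_rmssd, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("default presets order window rmssd by load class", {
  ds <- make_dataset(3, default_flight_plan(leg_duration = 60), seed = 20)
  feats <- purrr::map_dfr(seq_len(nrow(ds)), function(s) {
    f <- extract_features(clean_rr(ds$rr[[s]]))
    label_windows(f, ds$segments[[s]])
  })
  m <- tapply(feats$rmssd, feats$class_name, mean)
  expect_lt(m[["climbing"]], m[["leveling"]])
  expect_lt(m[["climbing"]], m[["descending"]])
  expect_lt(m[["descending"]], m[["leveling"]])
})

test_that("ground-truth segments respect the configured turn geometry", {
  plan <- default_flight_plan()
  segs <- true_turn_segments(plan, turn_rate = 1.5)
  expect_true(all(segs$heading_delta >= 20))
  expect_equal(segs$heading_delta / 1.5, segs$end_s - segs$start_s,
               tolerance = 1e-8)
  # non-overlapping and ordered
  expect_true(all(diff(segs$start_s) > 0))
  expect_true(all(segs$start_s[-1] >= head(segs$end_s, -1)))
  # RR timestamps span the track
  ds <- make_dataset(1, default_flight_plan(leg_duration = 30), seed = 2)
  rr <- ds$rr[[1]]; track <- ds$track[[1]]
  expect_gte(rr$time_s[1], track$time_s[1])
  expect_lte(max(rr$time_s), max(track$time_s))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(load_class_params(1, base_hr = 30, lf_amp = 1, hf_amp = 1),
               "base_hr")
  expect_error(load_class_params(1, 60, -1, 1), "amplitudes")
  expect_error(load_class_params(1, 60, 1, 1, lf_freq = 0.6), "frequencies")
  expect_error(load_class_params(1, 60, 1, 1, artifact_prob = 0.7),
               "artifact_prob")
  params <- default_class_params()
  expect_error(
    generate_rr_series(tibble::tibble(time_s = 0:500), tibble::tibble(),
                       params[params$class_id != 2, ]),
    "classes")
})
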