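test_that("window grid advances by the overlap-determined step", {
  rr <- constant_rr(800, 120)
  w <- sliding_windows(rr)
  expect_equal(w$start_s, c(0, 18, 36, 54, 72, 90))
  expect_equal(w$end_s - w$start_s, rep(30, 6))

  # zero overlap: disjoint contiguous windows
  w0 <- sliding_windows(rr, overlap = 0)
  expect_equal(w0$start_s, c(0, 30, 60, 90))

  expect_warning(w29 <- sliding_windows(constant_rr(800, 29)), "shorter")
  expect_equal(nrow(w29), 0)
  expect_error(sliding_windows(rr, overlap = 1), "overlap")
})

test_that("time-domain features match the brute-force oracle", {
  cases <- list(
    c(800, 810, 790, 805),
    c(700, 725, 750),
    withr::with_seed(3, stats::rnorm(50, 820, 40))
  )
  for (x in cases) {
    got <- hrv_time_domain(x)
    want <- oracle_time_domain(x)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], info = nm)
  }
  # hand-derived spot values
  expect_equal(hrv_time_domain(c(800, 810, 790, 805))$rmssd,
               sqrt((10^2 + 20^2 + 15^2) / 3), tolerance = 1e-12)
  t2 <- hrv_time_domain(c(700, 725, 750))
  expect_equal(t2$nni_20, 2)
  expect_equal(t2$pnni_20, 100)
  expect_error(hrv_time_domain(800), "too short")
})

test_that("zero-dispersion window collapses every spread measure", {
  td <- hrv_time_domain(rep(800, 10))
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$range_nni, 0)
  expect_equal(td$mean_hr, 75)
  expect_equal(td$min_hr, td$max_hr)
  expect_equal(triangular_index(rep(800, 10)), 1)
})

test_that("spectral power concentrates in the modulated band", {
  t0 <- cumsum(rep(0.5, 240))  # 2 Hz beats, 120 s
  hf_mod <- 800 + 50 * sin(2 * pi * 0.25 * t0)
  f_hf <- hrv_frequency_domain(hf_mod, t0)
  expect_gt(f_hf$hf, 10 * f_hf$lf)
  expect_gt(f_hf$hfnu, 90)

  lf_mod <- 800 + 50 * sin(2 * pi * 0.1 * t0)
  f_lf <- hrv_frequency_domain(lf_mod, t0)
  expect_gt(f_lf$lf, 10 * f_lf$hf)

  expect_equal(f_hf$lfnu + f_hf$hfnu, 100, tolerance = 1e-9)
  expect_equal(f_hf$total_power, f_hf$vlf + f_hf$lf + f_hf$hf,
               tolerance = 1e-9)
})

test_that("Poincare descriptors obey their algebraic identities", {
  x <- withr::with_seed(5, stats::rnorm(100, 800, 35))
  pc <- hrv_poincare(x)
  or <- oracle_poincare(x)
  expect_equal(pc$sd1, or$sd1, tolerance = 1e-12)
  expect_equal(pc$sd2, or$sd2, tolerance = 1e-12)
  expect_equal(pc$sd1, hrv_time_domain(x)$sdsd / sqrt(2), tolerance = 1e-9)
  expect_equal(pc$csi, pc$ratio_sd2_sd1)
  expect_equal(pc$Modified_csi, (4 * pc$sd2)^2 / (4 * pc$sd1))
  expect_equal(pc$cvi, log10(16 * pc$sd1 * pc$sd2))

  alt <- rep(c(800, 900), 20)
  pa <- hrv_poincare(alt)
  expect_equal(pa$sd1, stats::sd(diff(alt)) / sqrt(2), tolerance = 1e-9)
  expect_warning(hrv_poincare(rep(700, 5)), "degenerate")
})

test_that("triangular index counts histogram occupancy", {
  # uniform spread over k equally filled 7.8125 ms bins -> k
  k <- 5
  x <- rep(700 + (0:(k - 1)) * 1000 / 128 + 1, each = 8)
  expect_equal(triangular_index(x), k)
  withr::with_seed(8, {
    y <- stats::rnorm(200, 800, 50)
  })
  expect_gte(triangular_index(y), 1)
})

test_that("extract_features emits the full 30-feature vector per window", {
  rr <- constant_rr(750, 200)
  rr$rr_ms <- rr$rr_ms + withr::with_seed(2, stats::rnorm(nrow(rr), 0, 25))
  f <- extract_features(rr)
  expect_true(all(hrv_feature_names() %in% names(f)))
  expect_equal(length(hrv_feature_names()), 30)
  expect_gt(nrow(f), 0)
  # invariants per window
  expect_true(all(f$sdnn >= 0 & f$rmssd >= 0 & f$sd1 >= 0 & f$sd2 >= 0))
  expect_true(all(f$pnni_20 >= 0 & f$pnni_20 <= 100))
  expect_true(all(f$min_hr <= f$mean_hr & f$mean_hr <= f$max_hr))
  expect_equal(f$lfnu + f$hfnu, rep(100, nrow(f)), tolerance = 1e-9)
  expect_equal(f$ratio_sd2_sd1, f$sd2 / f$sd1, tolerance = 1e-12)
  expect_warning(short <- extract_features(constant_rr(800, 10)), "shorter")
  expect_equal(nrow(short), 0)
})

test_that("time-domain features agree with the oracle on 100 random windows", {
  withr::with_seed(21, {
    ok <- TRUE
    for (i in 1:100) {
      x <- stats::rnorm(sample(20:60, 1), stats::runif(1, 600, 1000),
                        stats::runif(1, 5, 60))
      got <- hrv_time_domain(x)
      want <- oracle_time_domain(x)
      for (nm in names(want)) {
        rel <- abs(got[[nm]] - want[[nm]]) / max(abs(want[[nm]]), 1e-9)
        if (rel > 0.01) ok <- FALSE
      }
    }
  })
  expect_true(ok)
})

test_that("order reversal leaves symmetric features unchanged", {
  x <- withr::with_seed(13, stats::rnorm(80, 800, 40))
  xr <- rev(x)
  expect_equal(hrv_time_domain(x)$sdnn, hrv_time_domain(xr)$sdnn)
  expect_equal(hrv_time_domain(x)$rmssd, hrv_time_domain(xr)$rmssd)
  expect_equal(triangular_index(x), triangular_index(xr))
  expect_equal(hrv_poincare(x)$sd1, hrv_poincare(xr)$sd1)
  expect_equal(hrv_poincare(x)$sd2, hrv_poincare(xr)$sd2)
})

test_that("scaling intervals scales the scale-equivariant features", {
  x <- withr::with_seed(17, stats::rnorm(60, 800, 30))
  c_ <- 1.37
  a <- hrv_time_domain(x); b <- hrv_time_domain(c_ * x)
  for (nm in c("mean_nni", "sdnn", "rmssd", "range_nni", "sdsd",
               "median_nni"))
    expect_equal(b[[nm]], c_ * a[[nm]], tolerance = 1e-9, info = nm)
  pa <- hrv_poincare(x); pb <- hrv_poincare(c_ * x)
  expect_equal(pb$sd1, c_ * pa$sd1, tolerance = 1e-9)
  expect_equal(pb$sd2, c_ * pa$sd2, tolerance = 1e-9)
})
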