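#' The 30 HRV feature names
#'
#' Canonical column order of the feature matrix: 16 time-domain, 7
#' frequency-domain, 6 Poincaré and 1 geometric feature.
#' @return Character vector of length 30.
#' @export
hrv_feature_names <- function() {
  c("mean_nni", "sdnn", "sdsd", "pnni_20", "pnni_50", "nni_20", "nni_50",
    "rmssd", "median_nni", "range_nni", "cvsd", "cvnni",
    "mean_hr", "max_hr", "min_hr", "std_hr",
    "lf", "hf", "lf_hf_ratio", "lfnu", "hfnu", "total_power", "vlf",
    "sd1", "sd2", "ratio_sd2_sd1", "csi", "cvi", "Modified_csi",
    "triangular_index")
}

#' The seven key turn-load indicators
#'
#' The short list of HRV features most reflective of turning cognitive load —
#' the triangular index, cvsd, rmssd, sdsd, min_hr, pnni_20 and nni_20 —
#' used as the default classifier input.
#' @return Character vector of length 7.
#' @export
key_hrv_features <- function() {
  c("triangular_index", "cvsd", "rmssd", "sdsd", "min_hr", "pnni_20",
    "nni_20")
}

#' Cut an RR series into sliding analysis windows
#'
#' Windows of `window_s` seconds advance by `window_s * (1 - overlap)` (18 s
#' at the 30 s / 40% defaults) from the series origin (the time of the first
#' beat, i.e. first interval start). Each window carries the NN intervals
#' whose end-beat time falls in `[start, start + window_s)`; a trailing
#' partial window is discarded, and windows with fewer than `min_intervals`
#' beats are dropped.
#'
#' @param rr Cleaned RR tibble (`time_s`, `rr_ms`).
#' @param window_s Window length, s (default 30).
#' @param overlap Overlap fraction of adjacent windows in `[0, 1)`
#'   (default 0.4).
#' @param min_intervals Minimum intervals for a valid window (default 4).
#' @return Tibble with `window_id`, `start_s`, `end_s`, `n_intervals`, and
#'   list-columns `intervals` (ms) and `times` (end-beat times, s). Empty
#'   (with a warning) when the series is shorter than one window.
#' @examples
#' rr <- tibble::tibble(time_s = seq(0.8, 120, by = 0.8),
#'                      rr_ms = rep(800, 150))
#' sliding_windows(rr)[, 1:4]
#' @export
sliding_windows <- function(rr, window_s = 30, overlap = 0.4,
                            min_intervals = 4) {
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  empty <- tibble(window_id = integer(), start_s = numeric(),
                  end_s = numeric(), n_intervals = integer(),
                  intervals = list(), times = list())
  if (nrow(rr) < 2) { warn("RR series too short for any window"); return(empty) }
  origin <- rr$time_s[1] - rr$rr_ms[1] / 1000
  last <- rr$time_s[nrow(rr)]
  if (last - origin < window_s) {
    warn("RR series shorter than one window")
    return(empty)
  }
  step <- window_s * (1 - overlap)
  starts <- seq(origin, last - window_s, by = step)
  out <- purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[i]; e <- s + window_s
    in_w <- rr$time_s >= s & rr$time_s < e
    tibble(start_s = s, end_s = e, n_intervals = sum(in_w),
           intervals = list(rr$rr_ms[in_w]), times = list(rr$time_s[in_w]))
  })
  out <- out[out$n_intervals >= min_intervals, ]
  dplyr::bind_cols(tibble(window_id = seq_len(nrow(out))), out)
}

#' Time-domain HRV features of one window
#'
#' Means, dispersion and successive-difference statistics of the NN intervals
#' plus instantaneous heart-rate statistics (HR per beat = 60000 / NN).
#' Standard deviations are sample SDs (denominator n - 1). `nni_20` /
#' `nni_50` count successive differences strictly greater than 20 / 50 ms in
#' magnitude; `pnni_*` are the same as percentages of all successive
#' differences.
#'
#' @param intervals Numeric NN intervals, ms (length >= 2).
#' @return One-row tibble with the 16 time-domain features.
#' @examples
#' hrv_time_domain(c(800, 810, 790, 805))
#' @export
hrv_time_domain <- function(intervals) {
  if (length(intervals) < 2) abort("window too short")
  x <- as.numeric(intervals)
  d <- diff(x)
  hr <- 60000 / x
  nd <- length(d)
  tibble(
    mean_nni = mean(x),
    sdnn = stats::sd(x),
    sdsd = stats::sd(d),
    pnni_20 = 100 * sum(abs(d) > 20) / nd,
    pnni_50 = 100 * sum(abs(d) > 50) / nd,
    nni_20 = sum(abs(d) > 20),
    nni_50 = sum(abs(d) > 50),
    rmssd = sqrt(mean(d^2)),
    median_nni = stats::median(x),
    range_nni = max(x) - min(x),
    cvsd = sqrt(mean(d^2)) / mean(x),
    cvnni = stats::sd(x) / mean(x),
    mean_hr = mean(hr),
    max_hr = max(hr),
    min_hr = min(hr),
    std_hr = stats::sd(hr)
  )
}

#' Poincaré-plot HRV features of one window
#'
#' From the lag-1 return map of NN intervals: `sd1` is the sample SD of
#' `(x[i+1] - x[i]) / sqrt(2)` (dispersion perpendicular to the identity
#' line, short-term variability), `sd2` the sample SD of
#' `(x[i+1] + x[i]) / sqrt(2)` (dispersion along it). The cardiac sympathetic
#' index `csi = sd2/sd1`, the modified sympathetic index
#' `(4 sd2)^2 / (4 sd1)`, and the cardiac vagal index
#' `cvi = log10(4 sd1 * 4 sd2)` follow the ellipse axes `T = 4 sd1`,
#' `L = 4 sd2`.
#'
#' Under the sample-SD convention `sd1 = sdsd / sqrt(2)` holds exactly.
#'
#' @param intervals Numeric NN intervals, ms (length >= 3).
#' @return One-row tibble: `sd1`, `sd2`, `ratio_sd2_sd1`, `csi`, `cvi`,
#'   `Modified_csi`. Ratio features are `NA` (with a warning) when `sd1 = 0`.
#' @export
hrv_poincare <- function(intervals) {
  if (length(intervals) < 3) abort("window too short")
  x <- as.numeric(intervals)
  x1 <- x[-length(x)]; x2 <- x[-1]
  sd1 <- stats::sd((x2 - x1) / sqrt(2))
  sd2 <- stats::sd((x2 + x1) / sqrt(2))
  if (sd1 == 0) {
    warn("degenerate Poincare plot (sd1 = 0); ratio features are NA")
    ratio <- NA_real_; mcsi <- NA_real_
  } else {
    ratio <- sd2 / sd1
    mcsi <- (4 * sd2)^2 / (4 * sd1)
  }
  cvi <- if (sd1 > 0 && sd2 > 0) log10((4 * sd1) * (4 * sd2)) else NA_real_
  tibble(sd1 = sd1, sd2 = sd2, ratio_sd2_sd1 = ratio, csi = ratio,
         cvi = cvi, Modified_csi = mcsi)
}

#' HRV triangular index of one window
#'
#' Total NN count divided by the modal bin count of the NN histogram at the
#' standard 1/128 s (7.8125 ms) bin width, bins aligned to zero.
#'
#' @param intervals Numeric NN intervals, ms (length >= 2).
#' @param bin_width Histogram bin width, ms (default 1000/128).
#' @return A number >= 1; exactly 1 when all intervals share one bin.
#' @export
triangular_index <- function(intervals, bin_width = 1000 / 128) {
  if (length(intervals) < 2) abort("window too short")
  bins <- floor(as.numeric(intervals) / bin_width)
  length(intervals) / max(table(bins))
}

#' Frequency-domain HRV features of one window
#'
#' The irregularly sampled NN series is linearly interpolated onto a uniform
#' 4 Hz grid, linearly detrended, Hann-tapered and turned into a one-segment
#' Welch (modified periodogram) power spectral density. Band powers (ms^2)
#' integrate the PSD over VLF `[0.003, 0.04)`, LF `[0.04, 0.15)` and HF
#' `[0.15, 0.4)` Hz; `total_power` is their sum, `lfnu`/`hfnu` normalise LF
#' and HF to their sum. Within a 30-s window the VLF band holds only a
#' fraction of a cycle, so `vlf` is retained for completeness but is not a
#' reliable estimate at this window length.
#'
#' @param intervals Numeric NN intervals, ms.
#' @param times End-beat times of the intervals, s (same length).
#' @param resample_hz Uniform resampling rate, Hz (default 4).
#' @return One-row tibble: `lf`, `hf`, `lf_hf_ratio`, `lfnu`, `hfnu`,
#'   `total_power`, `vlf`. `lf_hf_ratio` is `NA` (with a warning) when
#'   `hf = 0`.
#' @export
hrv_frequency_domain <- function(intervals, times, resample_hz = 4) {
  if (length(intervals) < 4) abort("window too short")
  if (length(intervals) != length(times)) abort("intervals/times length mismatch")
  grid <- seq(times[1], times[length(times)], by = 1 / resample_hz)
  x <- stats::approx(times, intervals, xout = grid, rule = 2)$y
  m <- length(x)
  # linear detrend
  tt <- seq_len(m)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))  # Hann
  xf <- stats::fft(x * w)
  # one-sided PSD in ms^2/Hz
  nf <- floor(m / 2) + 1
  psd <- (Mod(xf[seq_len(nf)])^2) / (resample_hz * sum(w^2))
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  freq <- (seq_len(nf) - 1) * resample_hz / m
  df <- resample_hz / m
  band <- function(lo, hi) sum(psd[freq >= lo & freq < hi]) * df
  vlf <- band(0.003, 0.04)
  lf <- band(0.04, 0.15)
  hf <- band(0.15, 0.4)
  if (hf == 0) {
    warn("zero HF power; lf_hf_ratio is NA")
    ratio <- NA_real_
  } else ratio <- lf / hf
  nu_den <- lf + hf
  tibble(
    lf = lf, hf = hf, lf_hf_ratio = ratio,
    lfnu = if (nu_den > 0) 100 * lf / nu_den else NA_real_,
    hfnu = if (nu_den > 0) 100 * hf / nu_den else NA_real_,
    total_power = vlf + lf + hf, vlf = vlf
  )
}

#' Extract the full 30-feature HRV matrix from an RR series
#'
#' Applies [sliding_windows()] and computes all 30 features per valid window.
#'
#' @param rr Cleaned RR tibble (`time_s`, `rr_ms`).
#' @param window_s,overlap,min_intervals Windowing parameters, see
#'   [sliding_windows()].
#' @param resample_hz Spectral resampling rate, Hz.
#' @return Tibble with `window_id`, `start_s`, `end_s`, `n_intervals` and the
#'   30 feature columns of [hrv_feature_names()]; zero rows for an empty or
#'   too-short series.
#' @examples
#' rr <- tibble::tibble(time_s = cumsum(rep(0.8, 150)),
#'                      rr_ms = 800 + 20 * sin(1:150 / 3))
#' extract_features(rr)[, c("window_id", "rmssd", "lf", "hf")]
#' @export
extract_features <- function(rr, window_s = 30, overlap = 0.4,
                             min_intervals = 4, resample_hz = 4) {
  wins <- sliding_windows(rr, window_s = window_s, overlap = overlap,
                          min_intervals = min_intervals)
  if (nrow(wins) == 0) {
    out <- tibble(window_id = integer(), start_s = numeric(),
                  end_s = numeric(), n_intervals = integer())
    for (nm in hrv_feature_names()) out[[nm]] <- numeric()
    return(out)
  }
  feats <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    iv <- wins$intervals[[i]]; tm <- wins$times[[i]]
    dplyr::bind_cols(
      hrv_time_domain(iv),
      hrv_frequency_domain(iv, tm, resample_hz = resample_hz),
      hrv_poincare(iv),
      tibble(triangular_index = triangular_index(iv))
    )[, hrv_feature_names()]
  })
  dplyr::bind_cols(wins[, c("window_id", "start_s", "end_s", "n_intervals")],
                   feats)
}
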