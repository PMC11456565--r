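#' Load-class parameter sets for the RR-interval generator
#'
#' One row per turn-load class (plus a baseline row, `class_id = 0`, active
#' outside turns) describing the instantaneous RR-interval model
#' `rr(t) = 60000 / base_hr + lf_amp sin(2 pi lf_freq t)
#'          + hf_amp sin(2 pi hf_freq t) + N(0, noise_sd)`.
#' `lf_amp`/`hf_amp` set sympathetic- and vagal-band modulation depth (ms);
#' `artifact_prob` is the per-beat probability that the observed interval is
#' corrupted (halved or doubled), emulating missed or false optical beat
#' detections.
#'
#' @param class_id Integer, 0 = baseline, 1 = climbing, 2 = leveling,
#'   3 = descending.
#' @param base_hr Mean heart rate, bpm, in `[40, 200]`.
#' @param lf_amp,hf_amp Modulation amplitudes, ms (>= 0).
#' @param lf_freq,hf_freq Modulation frequencies, Hz, in `(0, 0.5)`.
#' @param noise_sd Beat-to-beat Gaussian noise SD, ms.
#' @param artifact_prob Per-beat corruption probability, in `[0, 0.5)`.
#' @return A tibble with the validated columns plus `class_name`.
#' @export
load_class_params <- function(class_id, base_hr, lf_amp, hf_amp,
                              lf_freq = 0.1, hf_freq = 0.25,
                              noise_sd = 0, artifact_prob = 0) {
  n <- length(class_id)
  p <- tibble(
    class_id = as.integer(class_id),
    class_name = c("baseline", "climbing", "leveling", "descending")[class_id + 1L],
    base_hr = rep_len(base_hr, n),
    lf_amp = rep_len(lf_amp, n),
    hf_amp = rep_len(hf_amp, n),
    lf_freq = rep_len(lf_freq, n),
    hf_freq = rep_len(hf_freq, n),
    noise_sd = rep_len(noise_sd, n),
    artifact_prob = rep_len(artifact_prob, n)
  )
  if (any(p$base_hr < 40 | p$base_hr > 200))
    abort("base_hr must lie in [40, 200] bpm")
  if (any(p$lf_amp < 0 | p$hf_amp < 0))
    abort("modulation amplitudes must be >= 0")
  if (any(p$lf_freq <= 0 | p$lf_freq >= 0.5 | p$hf_freq <= 0 | p$hf_freq >= 0.5))
    abort("modulation frequencies must lie in (0, 0.5) Hz")
  if (any(p$artifact_prob < 0 | p$artifact_prob >= 0.5))
    abort("artifact_prob must lie in [0, 0.5)")
  p
}

#' Default generator presets per turn-load class
#'
#' Presets encode the qualitative autonomic picture of turning load: climbing
#' turns (highest load) have the highest heart rate and the most suppressed
#' vagal modulation, leveling turns (lowest load) the lowest rate and richest
#' variability, with descending turns between the two. Mean rates follow the
#' per-class heart-rate ordering observed in simulator studies
#' (climbing > descending > leveling); amplitude and noise values are free
#' parameters of this generator chosen to give short-term HRV (rmssd) in the
#' high-30s to high-40s ms range, ordered climbing < descending < leveling.
#'
#' @param artifact_prob Per-beat corruption probability (default 0.02).
#' @return A four-row parameter tibble (baseline + three classes).
#' @export
default_class_params <- function(artifact_prob = 0.02) {
  load_class_params(
    class_id = c(0L, 1L, 2L, 3L),
    base_hr  = c(85, 95, 90, 93),
    lf_amp   = c(40, 45, 55, 60),
    hf_amp   = c(45, 42, 55, 53),
    noise_sd = c(15, 16, 20, 19),
    artifact_prob = artifact_prob
  )
}

#' Simulate a beat-to-beat RR-interval series over a flight
#'
#' Emits beats by cumulative-interval construction: each beat time is the
#' previous beat time plus the current RR interval, whose mean and modulation
#' are taken from the load class active at that moment (a turn segment's class
#' inside turns, baseline outside). With probability `artifact_prob` the
#' *observed* interval is halved or doubled while the clean value is retained
#' alongside, so downstream artifact repair can be validated.
#'
#' @param track Telemetry tibble (defines the time span to cover).
#' @param segments Turn segments tibble with `start_s`, `end_s`, `class_id`
#'   (ground truth or detected).
#' @param params Parameter tibble from [load_class_params()]; must contain
#'   class ids 0 (baseline), 1, 2 and 3.
#' @param seed Integer seed for reproducibility.
#' @return Tibble with one row per interval: `time_s` (interval's end-beat
#'   time), `rr_ms` (observed), `rr_clean_ms` (pre-corruption), `is_artifact`.
#' @examples
#' plan <- default_flight_plan(leg_duration = 30)
#' track <- generate_flight_track(plan, seed = 1)
#' segs <- true_turn_segments(plan)
#' rr <- generate_rr_series(track, segs, seed = 1)
#' head(rr)
#' @export
generate_rr_series <- function(track, segments, params = default_class_params(),
                               seed = NULL) {
  need <- c(0L, 1L, 2L, 3L)
  if (!all(need %in% params$class_id))
    abort("params must include baseline (0) and all three load classes (1, 2, 3)")
  t0 <- track$time_s[1]
  t_end <- track$time_s[nrow(track)]
  # longest plausible interval: slowest class + margin
  if (t_end - t0 < max(60000 / params$base_hr) / 1000)
    abort("track too short for a single beat")
  prm <- as.data.frame(params[match(need, params$class_id), ])

  class_at <- function(t) {
    if (nrow(segments) == 0) return(1L)  # row index of baseline
    hit <- which(t >= segments$start_s & t < segments$end_s)
    if (length(hit) == 0) 1L else as.integer(segments$class_id[hit[1]]) + 1L
  }

  with_local_seed(seed, {
    n_guess <- ceiling((t_end - t0) * max(params$base_hr) / 60) + 16
    times <- numeric(n_guess); rr_obs <- numeric(n_guess)
    rr_clean <- numeric(n_guess); art <- logical(n_guess)
    t <- t0; i <- 0L
    repeat {
      row <- class_at(t)
      mu <- 60000 / prm$base_hr[row] +
        prm$lf_amp[row] * sin(2 * pi * prm$lf_freq[row] * t) +
        prm$hf_amp[row] * sin(2 * pi * prm$hf_freq[row] * t)
      rr <- max(mu + stats::rnorm(1, 0, prm$noise_sd[row]), 250)
      obs <- rr
      corrupted <- stats::runif(1) < prm$artifact_prob[row]
      if (corrupted) obs <- rr * sample(c(0.5, 2), 1)
      t_next <- t + obs / 1000
      if (t_next > t_end) break
      i <- i + 1L
      times[i] <- t_next; rr_obs[i] <- obs; rr_clean[i] <- rr
      art[i] <- corrupted
      t <- t_next
    }
    if (i == 0L) abort("track too short for a single beat")
    tibble(
      time_s = times[seq_len(i)],
      rr_ms = rr_obs[seq_len(i)],
      rr_clean_ms = rr_clean[seq_len(i)],
      is_artifact = art[seq_len(i)]
    )
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Each subject gets an independent RNG stream derived from the master seed,
#' so any subject is reproducible on its own. Tracks, RR series and
#' ground-truth turn segments are returned together as list-columns.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param plan Flight plan shared by all subjects.
#' @param params Load-class parameter tibble.
#' @param seed Master seed.
#' @param sample_interval,turn_rate,level_band Passed to the track generator
#'   and ground-truth segmenter.
#' @return Tibble with one row per subject: `subject`, `seed`, and
#'   list-columns `track`, `rr`, `segments`.
#' @examples
#' ds <- make_dataset(2, default_flight_plan(leg_duration = 30), seed = 7)
#' ds
#' @export
make_dataset <- function(n_subjects, plan = default_flight_plan(),
                         params = default_class_params(), seed = 1,
                         sample_interval = 1, turn_rate = 1.5,
                         level_band = 50) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  segs <- true_turn_segments(plan, turn_rate = turn_rate, level_band = level_band)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    s_seed <- derive_seed(seed, s)
    track <- generate_flight_track(plan, sample_interval = sample_interval,
                                   turn_rate = turn_rate, seed = s_seed)
    rr <- generate_rr_series(track, segs, params = params,
                             seed = derive_seed(s_seed, 1))
    tibble(subject = s, seed = s_seed,
           track = list(track), rr = list(rr), segments = list(segs))
  })
}
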