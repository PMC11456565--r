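#' Simulate flight telemetry for a plan
#'
#' Samples heading, altitude and speed at a fixed interval along the phase
#' schedule of `plan`: headings hold on straight legs and ramp at `turn_rate`
#' along the shorter circular arc during turns; altitude and speed ramp
#' linearly between their phase endpoints. Small Gaussian instrument jitter is
#' added to every channel.
#'
#' @param plan A flight-plan tibble (see [flight_plan()]).
#' @param sample_interval Telemetry sampling interval, s (default 1 s).
#' @param turn_rate Turn rate, deg/s (default 1.5, a gentle training turn).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param heading_jitter,altitude_jitter,speed_jitter Jitter SDs in deg, ft, kt.
#' @return Tibble with columns `time_s`, `heading_deg`, `altitude_ft`,
#'   `speed_kt`. Headings are wrapped to `[0, 360)`.
#' @examples
#' track <- generate_flight_track(default_flight_plan(), seed = 1)
#' head(track)
#' @export
generate_flight_track <- function(plan, sample_interval = 1, turn_rate = 1.5,
                                  seed = NULL, heading_jitter = 0.3,
                                  altitude_jitter = 5, speed_jitter = 1) {
  if (is.null(plan) || nrow(plan) == 0) abort("empty flight plan")
  stopifnot_scalar_number(sample_interval, "sample_interval", positive = TRUE)
  sched <- flight_schedule(plan, turn_rate)
  total <- sched$t1[nrow(sched)]
  time <- seq(0, total, by = sample_interval)
  idx <- findInterval(time, sched$t0, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  ph <- sched[idx, ]
  frac <- (time - ph$t0) / pmax(ph$t1 - ph$t0, .Machine$double.eps)
  frac <- pmin(pmax(frac, 0), 1)
  heading <- ph$h0 + frac * ph$dh
  altitude <- ph$a0 + frac * (ph$a1 - ph$a0)
  speed <- ph$s0 + frac * (ph$s1 - ph$s0)
  with_local_seed(seed, {
    heading <- heading + stats::rnorm(length(time), 0, heading_jitter)
    altitude <- altitude + stats::rnorm(length(time), 0, altitude_jitter)
    speed <- speed + stats::rnorm(length(time), 0, speed_jitter)
  })
  tibble(
    time_s = time,
    heading_deg = wrap_heading(heading),
    altitude_ft = altitude,
    speed_kt = speed
  )
}
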