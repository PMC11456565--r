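#' Construct a flight plan
#'
#' A flight plan is an ordered table of straight legs. Each leg holds a target
#' heading and speed; between consecutive legs the aircraft turns at a
#' configured rate along the shorter circular arc while ramping altitude from
#' the previous leg's end altitude to the next leg's start altitude. Altitude
#' may also drift linearly *within* a leg (start vs end altitude), which lets
#' the plan represent en-route descents between turns.
#'
#' @param heading Numeric vector of leg headings, degrees in `[0, 360)`.
#' @param altitude Numeric vector of leg end altitudes (ft), the altitude held
#'   just before the next turn. Must be positive.
#' @param speed Numeric vector of leg speeds (kt).
#' @param duration Numeric vector of straight-leg durations (s), or a single
#'   value recycled to all legs.
#' @param altitude_start Altitude (ft) at the start of each leg; defaults to
#'   `altitude` (level legs).
#'
#' @return A tibble with one row per leg and columns `leg`, `heading_deg`,
#'   `altitude_start_ft`, `altitude_ft`, `speed_kt`, `duration_s`.
#' @examples
#' flight_plan(heading = c(127, 40), altitude = c(1800, 3000),
#'             speed = 75, duration = 120)
#' @export
flight_plan <- function(heading, altitude, speed, duration,
                        altitude_start = altitude) {
  n <- length(heading)
  if (n < 1) abort("empty flight plan")
  speed <- rep_len(speed, n)
  duration <- rep_len(duration, n)
  altitude <- rep_len(altitude, n)
  altitude_start <- rep_len(altitude_start, n)
  if (any(heading < 0 | heading >= 360))
    abort("headings must lie in [0, 360)")
  if (any(altitude <= 0 | altitude_start <= 0))
    abort("altitudes must be positive")
  if (any(duration <= 0)) abort("leg durations must be positive")
  tibble(
    leg = seq_len(n),
    heading_deg = as.numeric(heading),
    altitude_start_ft = as.numeric(altitude_start),
    altitude_ft = as.numeric(altitude),
    speed_kt = as.numeric(speed),
    duration_s = as.numeric(duration)
  )
}

#' The nine-turn training flight plan
#'
#' The default plan reproduces a "preliminary screening" training circuit:
#' take-off leg on heading 127 at 1800 ft, followed by nine turns — two
#' climbing (to 3000 then 4000 ft), four leveling, and three descending —
#' ending on heading 127 at 2200 ft. The per-turn pre/post headings and
#' altitudes match the circuit's published turn table; one straight leg
#' (heading 180) carries an en-route descent from 3000 to 2500 ft so that the
#' fifth turn is flown level at 2500 ft.
#'
#' @param leg_duration Straight-leg duration in seconds (default 120 s).
#' @return A flight-plan tibble (see [flight_plan()]).
#' @examples
#' default_flight_plan()
#' @export
default_flight_plan <- function(leg_duration = 120) {
  flight_plan(
    heading        = c(127,   40,  330,  150,  180,  127,   37,  307,  217,  127),
    altitude       = c(1800, 3000, 4000, 4000, 2500, 2500, 2500, 2500, 2400, 2200),
    altitude_start = c(1800, 3000, 4000, 4000, 3000, 2500, 2500, 2500, 2400, 2200),
    speed          = c(75,    75,   95,   90,   90,   90,   90,   75,   75,   75),
    duration       = leg_duration
  )
}

# Phase table: alternating straight legs and turns, with linear start/end
# values per channel. Internal; drives both track sampling and ground truth.
flight_schedule <- function(plan, turn_rate) {
  if (nrow(plan) < 1) abort("empty flight plan")
  stopifnot_scalar_number(turn_rate, "turn_rate", positive = TRUE)
  phases <- list()
  t <- 0
  for (k in seq_len(nrow(plan))) {
    leg <- plan[k, ]
    phases[[length(phases) + 1]] <- tibble(
      phase = "leg", turn_id = NA_integer_,
      t0 = t, t1 = t + leg$duration_s,
      h0 = leg$heading_deg, dh = 0,
      a0 = leg$altitude_start_ft, a1 = leg$altitude_ft,
      s0 = leg$speed_kt, s1 = leg$speed_kt
    )
    t <- t + leg$duration_s
    if (k < nrow(plan)) {
      nxt <- plan[k + 1, ]
      dh <- signed_heading_step(leg$heading_deg, nxt$heading_deg)
      dur <- abs(dh) / turn_rate
      if (dur > 0) {
        phases[[length(phases) + 1]] <- tibble(
          phase = "turn", turn_id = k,
          t0 = t, t1 = t + dur,
          h0 = leg$heading_deg, dh = dh,
          a0 = leg$altitude_ft, a1 = nxt$altitude_start_ft,
          s0 = leg$speed_kt, s1 = nxt$speed_kt
        )
        t <- t + dur
      }
    }
  }
  dplyr::bind_rows(phases)
}

#' Ground-truth turn segments implied by a flight plan
#'
#' Derives, without simulation noise, the turn windows a plan's geometry
#' produces: start/end time of each heading ramp at the given turn rate, the
#' bracketing headings, the altitude change flown during the turn, and the
#' load class under the level-band rule (see [classify_turn()]).
#'
#' @param plan A flight-plan tibble.
#' @param turn_rate Heading change rate during turns, deg/s.
#' @param level_band Altitude tolerance (ft) separating leveling from
#'   climbing/descending turns.
#' @return Tibble with columns `turn_id`, `start_s`, `end_s`, `pre_heading`,
#'   `post_heading`, `heading_delta`, `altitude_change`, `class_id`,
#'   `class_name`.
#' @export
true_turn_segments <- function(plan, turn_rate = 1.5, level_band = 50) {
  sched <- flight_schedule(plan, turn_rate)
  turns <- sched[sched$phase == "turn", ]
  if (nrow(turns) == 0) {
    return(tibble(
      turn_id = integer(), start_s = numeric(), end_s = numeric(),
      pre_heading = numeric(), post_heading = numeric(),
      heading_delta = numeric(), altitude_change = numeric(),
      class_id = integer(), class_name = character()
    ))
  }
  post <- wrap_heading(turns$h0 + turns$dh)
  cls <- classify_turn(turns$a1 - turns$a0, level_band = level_band)
  tibble(
    turn_id = turns$turn_id,
    start_s = turns$t0, end_s = turns$t1,
    pre_heading = turns$h0, post_heading = post,
    heading_delta = heading_delta(turns$h0, post),
    altitude_change = turns$a1 - turns$a0,
    class_id = cls$class_id, class_name = cls$class_name
  )
}
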