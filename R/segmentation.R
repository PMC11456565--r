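#' Minimal circular heading difference
#'
#' The unsigned angular distance between two headings along the shorter arc,
#' in `[0, 180]` degrees. This is the "heading delta" of a turn: e.g. turning
#' from 040 to 330 is a 70-degree turn, not 290.
#'
#' @param pre,post Headings in degrees, each in `[0, 360)`. Vectorised.
#' @return Numeric vector of circular distances in `[0, 180]`.
#' @examples
#' heading_delta(127, 40)   # 87
#' heading_delta(40, 330)   # 70 (wraparound)
#' @export
heading_delta <- function(pre, post) {
  if (any(pre < 0 | pre >= 360 | post < 0 | post >= 360))
    abort("headings must lie in [0, 360)")
  d <- abs(pre - post) %% 360
  pmin(d, 360 - d)
}

#' Classify a turn's load class from its altitude change
#'
#' Altitude gained beyond `level_band` makes a climbing turn (class 1, highest
#' cognitive load), altitude lost beyond the band a descending turn (class 3,
#' intermediate load), and anything within the band a leveling turn (class 2,
#' lowest load).
#'
#' @param altitude_change Altitude change over the turn, ft. Vectorised.
#' @param level_band Half-width of the "relatively constant" altitude band,
#'   ft. The default 50 ft keeps a genuine 100 ft descent out of the band
#'   while absorbing instrument jitter.
#' @return Tibble with columns `class_id` (1/2/3) and `class_name`.
#' @examples
#' classify_turn(c(1200, -1000, 0))
#' @export
classify_turn <- function(altitude_change, level_band = 50) {
  id <- ifelse(altitude_change > level_band, 1L,
               ifelse(altitude_change < -level_band, 3L, 2L))
  tibble(class_id = as.integer(id),
         class_name = c("climbing", "leveling", "descending")[id])
}

#' Detect turns in flight telemetry
#'
#' A turn is a sustained heading ramp whose accumulated circular heading
#' change reaches at least `threshold` degrees. Detection works on the
#' per-step signed circular heading differences: steps are smoothed with a
#' short moving average, samples whose smoothed turn rate exceeds
#' `rate_threshold` are marked as turning, marked runs separated by less than
#' `merge_gap` seconds are merged, and a merged run is kept when its
#' accumulated heading change meets the threshold. Pre/post headings and
#' altitudes are medians over the `stable_n` samples bordering the run, so
#' jitter does not contaminate the turn geometry.
#'
#' The threshold semantics follow the 20-degrees-between-consecutive-data-
#' points rule read as an accumulated-ramp criterion: at 1 Hz telemetry a
#' gentle turn changes only a few degrees per sample, so the 20-degree
#' threshold applies to the total change across the ramp.
#'
#' @param track Telemetry tibble (`time_s`, `heading_deg`, `altitude_ft`).
#' @param threshold Minimum accumulated circular heading change, deg.
#' @param rate_threshold Smoothed turn rate (deg/s) above which a sample
#'   counts as turning.
#' @param merge_gap Merge adjacent detections closer than this, s.
#' @param level_band Passed to [classify_turn()].
#' @param stable_n Number of bordering stable samples used for pre/post
#'   medians.
#' @return Segments tibble: `turn_id`, `start_s`, `end_s`, `pre_heading`,
#'   `post_heading`, `heading_delta`, `altitude_change`, `class_id`,
#'   `class_name`. Zero rows when no turn is found.
#' @examples
#' plan <- default_flight_plan(leg_duration = 60)
#' track <- generate_flight_track(plan, seed = 1)
#' detect_turns(track)
#' @export
detect_turns <- function(track, threshold = 20, rate_threshold = 0.75,
                         merge_gap = 5, level_band = 50, stable_n = 5) {
  if (is.null(track) || nrow(track) == 0) abort("empty track")
  if (threshold <= 0) abort("threshold must be > 0")
  n <- nrow(track)
  empty <- tibble(
    turn_id = integer(), start_s = numeric(), end_s = numeric(),
    pre_heading = numeric(), post_heading = numeric(),
    heading_delta = numeric(), altitude_change = numeric(),
    class_id = integer(), class_name = character()
  )
  if (n < 3) return(empty)

  dt <- diff(track$time_s)
  step <- signed_heading_step(track$heading_deg[-n], track$heading_deg[-1])
  rate <- step / dt
  # centred moving average over 5 steps to suppress jitter
  k <- min(5L, length(rate))
  kern <- rep(1 / k, k)
  sm <- stats::filter(rate, kern, sides = 2)
  sm[is.na(sm)] <- 0
  turning <- abs(as.numeric(sm)) >= rate_threshold
  if (!any(turning)) return(empty)

  # merge runs separated by short gaps
  runs <- rle(turning)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  on_runs <- which(runs$values)
  merged <- list()
  cur <- c(starts[on_runs[1]], ends[on_runs[1]])
  for (r in on_runs[-1]) {
    gap_t <- track$time_s[starts[r]] - track$time_s[cur[2] + 1L]
    if (gap_t < merge_gap) cur[2] <- ends[r]
    else { merged[[length(merged) + 1]] <- cur; cur <- c(starts[r], ends[r]) }
  }
  merged[[length(merged) + 1]] <- cur

  segs <- purrr::map_dfr(merged, function(m) {
    a <- m[1]; b <- m[2]             # step indices: step i spans samples i, i+1
    total <- abs(sum(step[a:b]))
    if (total < threshold) return(NULL)
    pre_idx <- max(1L, a - stable_n):max(1L, a - 1L)
    post_idx <- min(n, b + 2L):min(n, b + 1L + stable_n)
    pre_h <- circular_median(track$heading_deg[pre_idx])
    post_h <- circular_median(track$heading_deg[post_idx])
    alt_change <- stats::median(track$altitude_ft[post_idx]) -
      stats::median(track$altitude_ft[pre_idx])
    tibble(
      start_s = track$time_s[a], end_s = track$time_s[b + 1L],
      pre_heading = pre_h, post_heading = post_h,
      heading_delta = heading_delta(pre_h, post_h),
      altitude_change = alt_change
    )
  })
  if (nrow(segs) == 0) return(empty)
  cls <- classify_turn(segs$altitude_change, level_band = level_band)
  dplyr::bind_cols(tibble(turn_id = seq_len(nrow(segs))), segs, cls)
}

# Median direction of a set of headings, safe across the 0/360 wrap: unwrap
# relative to the first heading, take the median, wrap back.
circular_median <- function(h) {
  rel <- signed_heading_step(h[1], h)
  wrap_heading(h[1] + stats::median(rel))
}

#' Assign turn-load labels to feature windows
#'
#' A window inherits the class of the turn segment with which its
#' time-overlap fraction (overlap duration over window duration) is largest,
#' provided that fraction reaches `min_overlap`; windows below the cut are
#' excluded (label `NA`) and dropped from classification datasets.
#'
#' @param windows Window tibble with `start_s`, `end_s` columns (e.g. from
#'   [extract_features()]).
#' @param segments Segments tibble with `start_s`, `end_s`, `class_id`.
#' @param min_overlap Minimum overlap fraction, default 0.5.
#' @return `windows` with `segment_id`, `overlap`, `class_id` and
#'   `class_name` columns added; unassigned windows carry `NA`.
#' @export
label_windows <- function(windows, segments, min_overlap = 0.5) {
  if (nrow(windows) == 0) {
    return(dplyr::mutate(windows, segment_id = integer(), overlap = numeric(),
                         class_id = integer(), class_name = character()))
  }
  lab <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w0 <- windows$start_s[i]; w1 <- windows$end_s[i]
    if (nrow(segments) == 0)
      return(tibble(segment_id = NA_integer_, overlap = 0))
    ov <- pmax(0, pmin(w1, segments$end_s) - pmax(w0, segments$start_s)) /
      (w1 - w0)
    j <- which.max(ov)
    tibble(segment_id = ifelse(ov[j] > 0, j, NA_integer_), overlap = ov[j])
  })
  assigned <- !is.na(lab$segment_id) & lab$overlap >= min_overlap
  class_id <- ifelse(assigned,
                     as.integer(segments$class_id[lab$segment_id]), NA_integer_)
  dplyr::mutate(
    windows,
    segment_id = ifelse(assigned, lab$segment_id, NA_integer_),
    overlap = lab$overlap,
    class_id = as.integer(class_id),
    class_name = c("climbing", "leveling", "descending")[class_id]
  )
}
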