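#' Flag anomalous RR intervals
#'
#' An interval is flagged when it deviates from its local running median by
#' more than `rel_threshold` (relative deviation). The local median is taken
#' over the 5 nearest intervals by position, including the interval itself —
#' a centred window in the interior, one-sided at the edges — a local-median
#' rule in the style of classic RR artifact filters. Including the candidate
#' in a 5-point median leaves the estimate robust to isolated artifacts while
#' keeping edge behaviour sane (a valid edge beat next to an artifact is not
#' itself flagged).
#'
#' @param rr RR tibble with at least `time_s` and `rr_ms` columns.
#' @param rel_threshold Relative deviation threshold, in `(0, 1)`
#'   (default 0.2 = 20%).
#' @return The input tibble with a logical `flagged` column added; the rule
#'   and threshold are recorded in attributes `artifact_rule` and
#'   `artifact_threshold`.
#' @examples
#' rr <- tibble::tibble(time_s = cumsum(c(.8, .805, 1.6, .81, .795)),
#'                      rr_ms = c(800, 805, 1600, 810, 795))
#' detect_artifacts(rr)$flagged
#' @export
detect_artifacts <- function(rr, rel_threshold = 0.2) {
  if (rel_threshold <= 0 || rel_threshold >= 1)
    abort("rel_threshold must lie in (0, 1)")
  x <- rr$rr_ms
  n <- length(x)
  if (n < 3) {
    warn("RR series shorter than 3 intervals; nothing flagged")
    flags <- rep(FALSE, n)
  } else {
    win <- 5L  # window of the 5 nearest intervals, self included
    flags <- vapply(seq_len(n), function(j) {
      lo <- max(1L, j - 2L); hi <- min(n, j + 2L)
      # top up one-sided at the edges
      while (hi - lo + 1L < win && (lo > 1L || hi < n)) {
        if (lo > 1L) lo <- lo - 1L
        if (hi - lo + 1L < win && hi < n) hi <- hi + 1L
      }
      m <- stats::median(x[lo:hi])
      abs(x[j] - m) / m > rel_threshold
    }, logical(1))
  }
  out <- rr
  out$flagged <- flags
  attr(out, "artifact_rule") <- "local_median_5"
  attr(out, "artifact_threshold") <- rel_threshold
  out
}

#' Repair flagged RR intervals by linear interpolation
#'
#' Each flagged run strictly between two valid intervals `y_i` and `y_(i+n)`
#' is replaced by the linear interpolant
#' `y_(i+k) = y_i + k (y_(i+n) - y_i) / n`, `k = 1, ..., n-1`. Flagged runs
#' touching either end of the series have no bracketing value and are dropped
#' with a warning rather than extrapolated. Beat times are rebuilt by
#' cumulative summation of the corrected intervals from the original first
#' beat time.
#'
#' @param rr RR tibble carrying a logical `flagged` column (from
#'   [detect_artifacts()]).
#' @return A tibble `time_s`, `rr_ms` with flagged interior intervals replaced
#'   and flagged edge intervals removed; equals the input exactly when nothing
#'   is flagged.
#' @examples
#' rr <- detect_artifacts(tibble::tibble(
#'   time_s = cumsum(c(.8, .805, 1.6, .81, .795)),
#'   rr_ms = c(800, 805, 1600, 810, 795)))
#' interpolate_anomalies(rr)$rr_ms
#' @export
interpolate_anomalies <- function(rr) {
  if (is.null(rr$flagged)) abort("`rr` must carry a `flagged` column; run detect_artifacts() first")
  x <- rr$rr_ms
  flags <- rr$flagged
  n <- length(x)
  if (!any(flags)) return(tibble(time_s = rr$time_s, rr_ms = x))

  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- rep(TRUE, n)
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    if (a == 1L || b == n) {
      warn("flagged run touches the series edge; intervals dropped")
      keep[a:b] <- FALSE
      next
    }
    yi <- x[a - 1L]; yn <- x[b + 1L]
    m <- b - a + 2L                      # gap size n: run length + 1
    x[a:b] <- yi + seq_len(b - a + 1L) * (yn - yi) / m
  }
  x <- x[keep]
  t0 <- rr$time_s[1] - rr$rr_ms[1] / 1000  # first beat time
  tibble(time_s = t0 + cumsum(x) / 1000, rr_ms = x)
}

#' Detect-and-repair convenience wrapper
#'
#' @inheritParams detect_artifacts
#' @return Cleaned RR tibble (`time_s`, `rr_ms`).
#' @export
clean_rr <- function(rr, rel_threshold = 0.2) {
  interpolate_anomalies(detect_artifacts(rr, rel_threshold))
}
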