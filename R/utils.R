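#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Run code with a temporary RNG state. `seed = NULL` leaves the RNG alone.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit seed derived from a master seed; stays inside the
# 32-bit integer range expected by set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 1000003 * as.double(index)) %% 2147483647)
}

wrap_heading <- function(x) x %% 360

# Signed circular step from `from` to `to`, in (-180, 180]. A 180-degree
# ambiguity resolves to +180 (clockwise), a fixed tie-break.
signed_heading_step <- function(from, to) {
  d <- (to - from) %% 360
  ifelse(d > 180, d - 360, d)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
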