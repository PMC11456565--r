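#' Build sequence samples from labeled feature windows
#'
#' A sequence sample is a run of `seq_len` consecutive overlapping windows
#' that all belong to the same turn segment, so the recurrent models see
#' genuine within-turn time structure. Windows are grouped by subject and
#' segment, ordered by start time, and every contiguous run of `seq_len`
#' windows (stride 1) becomes one sample carrying the segment's load class.
#' Turns spanning fewer than `seq_len` labeled windows contribute no sample.
#'
#' @param labeled Feature tibble with `subject`, `segment_id`, `class_id`,
#'   `start_s` and feature columns (from [extract_features()] +
#'   [label_windows()]).
#' @param feature_names Feature columns to include as the per-step vector.
#' @param seq_len Windows per sample (default 3).
#' @return Tibble with `sample_id`, `subject`, `segment_id`, `class_id` and a
#'   `steps` list-column of `seq_len x length(feature_names)` matrices.
#' @export
make_sequences <- function(labeled, feature_names, seq_len = 3) {
  dat <- labeled[!is.na(labeled$class_id) & !is.na(labeled$segment_id), ]
  if (nrow(dat) == 0 || length(feature_names) == 0) {
    return(tibble(sample_id = integer(), subject = integer(),
                  segment_id = integer(), class_id = integer(),
                  steps = list()))
  }
  if (is.null(dat$subject)) dat$subject <- 1L
  out <- dat |>
    dplyr::arrange(.data$subject, .data$segment_id, .data$start_s) |>
    dplyr::group_by(.data$subject, .data$segment_id) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < seq_len) return(NULL)
      purrr::map_dfr(seq_len(n - seq_len + 1), function(i) {
        steps <- as.matrix(g[i:(i + seq_len - 1), feature_names, drop = FALSE])
        dimnames(steps) <- list(NULL, feature_names)
        tibble(subject = key$subject, segment_id = key$segment_id,
               class_id = g$class_id[1], steps = list(steps))
      })
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble(sample_id = integer(), subject = integer(),
                  segment_id = integer(), class_id = integer(),
                  steps = list()))
  }
  dplyr::bind_cols(tibble(sample_id = seq_len(nrow(out))), out)
}

#' Stratified train/test split of sequence samples
#'
#' Random split stratified by class: each class contributes
#' `round(train_frac * n_class)` samples to the training set. Disjoint and
#' exhaustive; reproducible per seed.
#'
#' @param samples Sequence-sample tibble with `class_id`.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_samples <- function(samples, train_frac = 0.7, seed = 1) {
  if (nrow(samples) < 10) abort("need at least 10 samples to split")
  counts <- table(samples$class_id)
  if (any(counts < 2)) abort("every class needs at least 2 samples")
  with_local_seed(seed, {
    idx_train <- unlist(lapply(unique(samples$class_id), function(cl) {
      ix <- which(samples$class_id == cl)
      n_tr <- max(1L, min(length(ix) - 1L, round(train_frac * length(ix))))
      sample(ix, n_tr)
    }))
  })
  list(train = samples[sort(idx_train), ],
       test = samples[setdiff(seq_len(nrow(samples)), idx_train), ])
}

#' Balance classes by up-sampling
#'
#' Minority classes are resampled with replacement until every class matches
#' the majority count. Every emitted sample is a copy of an input sample of
#' the same class.
#'
#' @param samples Sequence-sample tibble with `class_id` (>= 1 sample per
#'   class present).
#' @param seed Integer seed.
#' @return Balanced tibble (class counts all equal to the majority count).
#' @export
upsample_balance <- function(samples, seed = 1) {
  counts <- table(samples$class_id)
  if (any(counts == 0) || length(counts) == 0) abort("empty class")
  target <- max(counts)
  with_local_seed(seed, {
    idx <- unlist(lapply(names(counts), function(cl) {
      ix <- which(samples$class_id == as.integer(cl))
      if (length(ix) == target) ix
      else c(ix, sample(ix, target - length(ix), replace = TRUE))
    }))
  })
  samples[idx, ]
}

#' Fit and apply per-feature min-max scaling
#'
#' Scaling ranges are fitted on the training samples only (over all sequence
#' steps) and applied to both sets, mapping each feature's training range to
#' `[0, 1]`. Constant features map to 0. Test values outside the training
#' range land outside `[0, 1]`, which is expected and left untouched.
#'
#' @param train Sequence tibble whose `steps` matrices define the ranges.
#' @param apply_to Optional further tibble(s) to scale: a tibble or a list of
#'   tibbles.
#' @return List with `train`, `apply_to` (same shape as given) and `scaler`
#'   (tibble `feature`, `min`, `max`).
#' @export
normalize01 <- function(train, apply_to = NULL) {
  if (nrow(train) == 0) abort("empty training set")
  all_steps <- do.call(rbind, train$steps)
  mins <- apply(all_steps, 2, min)
  maxs <- apply(all_steps, 2, max)
  rng <- maxs - mins
  scale_steps <- function(m) {
    out <- sweep(m, 2, mins, "-")
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
    out
  }
  scale_tbl <- function(tbl) {
    tbl$steps <- lapply(tbl$steps, scale_steps)
    tbl
  }
  one <- is.data.frame(apply_to)
  if (one) apply_to <- list(apply_to)
  out_apply <- if (is.null(apply_to)) NULL else lapply(apply_to, scale_tbl)
  list(
    train = scale_tbl(train),
    apply_to = if (one) out_apply[[1]] else out_apply,
    scaler = tibble(feature = colnames(all_steps) %||% seq_along(mins),
                    min = unname(mins), max = unname(maxs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flatten_steps <- function(samples) {
  do.call(rbind, lapply(samples$steps, function(m) as.numeric(t(m))))
}
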