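# Independent brute-force oracles, written loop-first and kept deliberately
# separate from the package's vectorised implementations.

oracle_time_domain <- function(x) {
  n <- length(x)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- x[i + 1] - x[i]
  sample_sd <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  hr <- numeric(n)
  for (i in seq_len(n)) hr[i] <- 60000 / x[i]
  list(
    mean_nni = sum(x) / n,
    median_nni = stats::median(x),
    range_nni = max(x) - min(x),
    sdnn = sample_sd(x),
    sdsd = sample_sd(d),
    rmssd = sqrt(sum(d^2) / length(d)),
    nni_20 = sum(abs(d) > 20),
    nni_50 = sum(abs(d) > 50),
    pnni_20 = 100 * sum(abs(d) > 20) / length(d),
    pnni_50 = 100 * sum(abs(d) > 50) / length(d),
    cvsd = sqrt(sum(d^2) / length(d)) / (sum(x) / n),
    cvnni = sample_sd(x) / (sum(x) / n),
    mean_hr = sum(hr) / n,
    max_hr = max(hr),
    min_hr = min(hr),
    std_hr = sample_sd(hr)
  )
}

oracle_poincare <- function(x) {
  n <- length(x)
  u <- numeric(n - 1); v <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    u[i] <- (x[i + 1] - x[i]) / sqrt(2)
    v[i] <- (x[i + 1] + x[i]) / sqrt(2)
  }
  list(sd1 = stats::sd(u), sd2 = stats::sd(v))
}

# Mann-Whitney pair-counting AUC (ties count 1/2).
oracle_auc_paircount <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Macro-F1 straight from a confusion matrix, by per-class arithmetic.
oracle_macro_f1 <- function(conf) {
  f1s <- numeric(nrow(conf))
  for (k in seq_len(nrow(conf))) {
    tp <- conf[k, k]
    prec <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
    f1s[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1s)
}

# Constant-rate RR tibble helper.
constant_rr <- function(rr_ms, duration_s) {
  times <- seq(rr_ms / 1000, duration_s, by = rr_ms / 1000)
  tibble::tibble(time_s = times, rr_ms = rep(rr_ms, length(times)))
}

rr_from_intervals <- function(intervals_ms, t0 = 0) {
  tibble::tibble(time_s = t0 + cumsum(intervals_ms) / 1000,
                 rr_ms = intervals_ms)
}

# A small labeled feature tibble with three well-separated classes, for
# screening and sequence tests.
toy_labeled_features <- function(n_per_class = 30, seed = 1, sd = 1,
                                 shift = c(0, 1, 2)) {
  withr::with_seed(seed, {
    purrr::map_dfr(1:3, function(cl) {
      tibble::tibble(
        subject = rep(1:3, length.out = n_per_class),
        segment_id = cl,
        class_id = cl,
        start_s = seq(0, by = 18, length.out = n_per_class),
        rmssd = stats::rnorm(n_per_class, 40 + 10 * shift[cl], sd * 5),
        sdnn = stats::rnorm(n_per_class, 50 + 8 * shift[cl], sd * 6),
        mean_hr = stats::rnorm(n_per_class, 90 - 3 * shift[cl], sd * 2)
      )
    })
  })
}
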