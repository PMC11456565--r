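#' ROC curve by threshold sweep
#'
#' Standard binary ROC: scores are sorted decreasing and the operating point
#' steps through every distinct score threshold; tied scores move the curve
#' diagonally in a single step. Both coordinates are monotone non-decreasing.
#'
#' @param y_true Binary truth (0/1 or logical), both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return Tibble `threshold`, `fpr`, `tpr`, beginning at (0, 0) and ending
#'   at (1, 1).
#' @examples
#' roc_curve(c(0, 0, 1, 1), c(.1, .4, .35, .8))
#' @export
roc_curve <- function(y_true, scores) {
  y <- as.integer(as.logical(y_true))
  if (length(unique(y)) < 2) abort("both classes must be present")
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct score
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / nn),
    tpr = c(0, tp[last] / np)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of [roc_curve()]; equals the Mann–Whitney
#' pair-counting probability that a random positive outscores a random
#' negative (ties counting one half).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  rc <- roc_curve(y_true, scores)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Classification report for a 3-class probability matrix
#'
#' Predicted class is the probability argmax. Precision, recall and F1 are
#' macro-averaged (unweighted mean over classes, robust under imbalance);
#' AUC is computed one-vs-rest per class from that class's probability
#' column, with the macro AUC their mean. A class absent from the truth
#' yields `NA` for its AUC (and is skipped in per-class F1 terms where
#' undefined, treated as 0 per the usual convention when a class is predicted
#' but never true).
#'
#' @param y_true Integer truth labels (1 = climbing, 2 = leveling,
#'   3 = descending).
#' @param y_prob Matrix `n x 3` of class probabilities (rows on the
#'   simplex).
#' @param model_name Optional label carried into the report.
#' @return An `turnload_report` object: list with `model_name`, `accuracy`,
#'   `precision`, `recall`, `f1` (macro), `per_class_auc`, `macro_auc`,
#'   `confusion` (3x3, rows = truth), `n_test`.
#' @examples
#' pr <- matrix(c(.8, .1, .1, .1, .8, .1, .1, .1, .8), 3, byrow = TRUE)
#' classification_metrics(1:3, pr)$f1
#' @export
classification_metrics <- function(y_true, y_prob, model_name = "model") {
  y_true <- as.integer(y_true)
  if (!is.matrix(y_prob) || ncol(y_prob) != 3)
    abort("y_prob must be an n x 3 probability matrix")
  if (nrow(y_prob) != length(y_true)) abort("length mismatch")
  pred <- max.col(y_prob, ties.method = "first")
  conf <- table(factor(y_true, 1:3), factor(pred, 1:3))
  conf <- matrix(as.integer(conf), 3, 3,
                 dimnames = list(truth = c("climbing", "leveling", "descending"),
                                 pred = c("climbing", "leveling", "descending")))
  acc <- sum(diag(conf)) / sum(conf)
  prec <- rec <- f1 <- numeric(3)
  for (k in 1:3) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  auc <- vapply(1:3, function(k) {
    if (length(unique(y_true == k)) < 2) return(NA_real_)
    roc_auc(y_true == k, y_prob[, k])
  }, numeric(1))
  structure(list(
    model_name = model_name, accuracy = acc,
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    per_class_f1 = f1, per_class_auc = auc,
    macro_auc = mean(auc, na.rm = TRUE),
    confusion = conf, n_test = length(y_true)
  ), class = "turnload_report")
}

#' @export
print.turnload_report <- function(x, ...) {
  cat(sprintf("<turnload_report> %s (n = %d)\n", x$model_name, x$n_test))
  cat(sprintf("  accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f | AUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$macro_auc))
  invisible(x)
}

#' Rank models by macro-F1
#'
#' Models are sorted by macro-F1 descending, ties broken by macro AUC — the
#' F1-first reading of multi-metric evaluation under class imbalance.
#'
#' @param reports List of `turnload_report` objects (>= 2).
#' @return Tibble `rank`, `model`, `f1`, `accuracy`, `precision`, `recall`,
#'   `macro_auc`.
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) abort("need at least 2 reports to compare")
  tab <- purrr::map_dfr(reports, function(r) {
    tibble(model = r$model_name, f1 = r$f1, accuracy = r$accuracy,
           precision = r$precision, recall = r$recall,
           macro_auc = r$macro_auc)
  })
  tab <- tab[order(-tab$f1, -tab$macro_auc), ]
  dplyr::bind_cols(tibble(rank = seq_len(nrow(tab))), tab)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class metrics of a classification report
#' @param x A `turnload_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `auc`, `n_true`.
#' @export
tidy.turnload_report <- function(x, ...) {
  cls <- rownames(x$confusion)
  prec <- vapply(1:3, function(k) {
    s <- sum(x$confusion[, k]); if (s > 0) x$confusion[k, k] / s else 0
  }, numeric(1))
  rec <- vapply(1:3, function(k) {
    s <- sum(x$confusion[k, ]); if (s > 0) x$confusion[k, k] / s else 0
  }, numeric(1))
  tibble(class = cls, precision = prec, recall = rec,
         f1 = x$per_class_f1, auc = x$per_class_auc,
         n_true = rowSums(x$confusion))
}

#' One-row summary of a classification report
#' @param x A `turnload_report`.
#' @param ... Unused.
#' @export
glance.turnload_report <- function(x, ...) {
  tibble(model = x$model_name, accuracy = x$accuracy,
         precision = x$precision, recall = x$recall, f1 = x$f1,
         macro_auc = x$macro_auc, n_test = x$n_test)
}

#' Training history of a fitted sequence model
#' @param x A trained `turnload_nn` model.
#' @param ... Unused.
#' @return The epoch-by-epoch loss history tibble.
#' @export
tidy.turnload_nn <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history; train it first")
  x$history
}

#' One-row summary of a fitted sequence model
#' @param x A `turnload_nn` model.
#' @param ... Unused.
#' @export
glance.turnload_nn <- function(x, ...) {
  tibble(
    architecture = if (x$use_attention) "lstm_attention" else "lstm",
    n_parameters = n_parameters(x),
    input_dim = x$input_dim,
    trained = x$trained,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_loss = if (is.null(x$history) || all(is.na(x$history$val_loss)))
      NA_real_ else min(x$history$val_loss, na.rm = TRUE)
  )
}
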