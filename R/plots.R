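#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_point
#'   geom_abline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a flight track's heading and altitude channels
#'
#' @param track Telemetry tibble.
#' @param segments Optional segments tibble to shade detected turns.
#' @return A ggplot object (heading and altitude facets over time).
#' @export
plot_track <- function(track, segments = NULL) {
  long <- tidyr::pivot_longer(
    track[, c("time_s", "heading_deg", "altitude_ft")],
    -"time_s", names_to = "channel", values_to = "value")
  p <- ggplot(long, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ .data$channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      aes(xmin = .data$start_s, xmax = .data$end_s, ymin = -Inf, ymax = Inf,
          fill = .data$class_name),
      alpha = 0.2, inherit.aes = FALSE) +
      labs(fill = "turn class")
  }
  p
}

#' One-vs-rest ROC curves for one or more models
#'
#' @param points Tibble from [roc_points()], possibly row-bound across
#'   models.
#' @return A ggplot object.
#' @export
plot_roc <- function(points) {
  ggplot(points, aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    facet_wrap(~ .data$model) +
    labs(x = "false positive rate", y = "true positive rate",
         colour = "class (one-vs-rest)") +
    theme_minimal()
}

#' Assemble one-vs-rest ROC points for plotting
#'
#' @param y_true Integer truth labels (1/2/3).
#' @param y_prob `n x 3` probability matrix.
#' @param model_name Label attached to the points.
#' @return Tibble `model`, `class`, `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, y_prob, model_name = "model") {
  cls <- c("climbing", "leveling", "descending")
  purrr::map_dfr(1:3, function(k) {
    if (length(unique(y_true == k)) < 2) return(NULL)
    rc <- roc_curve(y_true == k, y_prob[, k])
    dplyr::bind_cols(tibble(model = model_name, class = cls[k]), rc)
  })
}

#' Training-history curve of a fitted sequence model
#'
#' @param object A trained `turnload_nn` model.
#' @param ... Unused.
#' @return A ggplot of train and validation loss per epoch.
#' @export
autoplot.turnload_nn <- function(object, ...) {
  h <- tidy.turnload_nn(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "series",
                              values_to = "loss")
  ggplot(long[!is.na(long$loss), ],
         aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' Per-class metric bars of a classification report
#'
#' @param object A `turnload_report`.
#' @param ... Unused.
#' @return A ggplot of per-class precision/recall/F1.
#' @export
autoplot.turnload_report <- function(object, ...) {
  td <- tidy.turnload_report(object)
  long <- tidyr::pivot_longer(td[, c("class", "precision", "recall", "f1")],
                              -"class", names_to = "metric",
                              values_to = "value")
  ggplot(long, aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    labs(x = NULL, y = NULL, title = object$model_name) +
    theme_minimal()
}
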