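#' Normality flags per feature
#'
#' One-sample Kolmogorov–Smirnov test of each feature column against a normal
#' distribution with the sample's own mean and SD; a feature is flagged
#' normal when the K-S p-value is at least `alpha`. Estimating the reference
#' parameters from the same sample biases the test toward non-rejection
#' (the Lilliefors caveat), mirroring the common point-and-click usage the
#' screen emulates; constant features are non-normal by convention.
#'
#' @param features Feature tibble; columns in `feature_names` are tested.
#' @param feature_names Character vector of columns to test (default: the 30
#'   HRV features present in `features`).
#' @param alpha Significance level for the normality decision.
#' @return Tibble with columns `feature` and `normal` (logical).
#' @export
normality_flags <- function(features, feature_names = NULL, alpha = 0.05) {
  if (is.null(feature_names))
    feature_names <- intersect(hrv_feature_names(), names(features))
  purrr::map_dfr(feature_names, function(nm) {
    x <- features[[nm]]
    x <- x[is.finite(x)]
    if (length(x) < 3) abort(sprintf("feature `%s` has < 3 observations", nm))
    if (stats::sd(x) == 0) {
      warn(sprintf("feature `%s` is constant; flagged non-normal", nm))
      return(tibble(feature = nm, normal = FALSE))
    }
    p <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    tibble(feature = nm, normal = p >= alpha)
  })
}

#' Compare one feature across the three turn-load classes
#'
#' One-way ANOVA when the feature is normal, Kruskal–Wallis otherwise; all
#' three classes must be present with at least two observations each.
#' Identical constant groups make the Kruskal–Wallis statistic degenerate;
#' that case is reported as p = 1 with a warning.
#'
#' @param values Numeric feature values.
#' @param class_id Integer class labels (1 = climbing, 2 = leveling,
#'   3 = descending), same length.
#' @param normal Logical: route to ANOVA (`TRUE`) or Kruskal–Wallis.
#' @param feature Feature name carried into the result.
#' @param alpha Selection threshold.
#' @return One-row tibble: `feature`, `normal`, `test_used`, `p_value`,
#'   `mean_climbing`, `mean_leveling`, `mean_descending`, `selected`.
#' @export
group_comparison <- function(values, class_id, normal, feature = "feature",
                             alpha = 0.05) {
  keep <- is.finite(values) & !is.na(class_id)
  values <- values[keep]; class_id <- as.integer(class_id[keep])
  counts <- table(factor(class_id, levels = 1:3))
  if (any(counts < 2)) abort("class absent")
  g <- factor(class_id, levels = 1:3)
  means <- tapply(values, g, mean)
  if (stats::sd(values) == 0) {
    warn("degenerate comparison on constant values; p = 1")
    p <- 1
    test <- if (normal) "ANOVA" else "KW"
  } else if (normal) {
    fit <- stats::aov(values ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    test <- "ANOVA"
  } else {
    p <- stats::kruskal.test(values, g)$p.value
    test <- "KW"
  }
  tibble(
    feature = feature, normal = normal, test_used = test, p_value = p,
    mean_climbing = unname(means[1]), mean_leveling = unname(means[2]),
    mean_descending = unname(means[3]), selected = p < alpha
  )
}

#' Screen HRV features across turn-load classes
#'
#' The full screening procedure: per-feature K-S normality test routing each
#' feature to one-way ANOVA (normal) or Kruskal–Wallis (non-normal) across
#' the three classes, at significance threshold `alpha`. Windows are pooled
#' across subjects by default; `unit = "subject"` first averages windows
#' within subject x class, a sensitivity analysis for the pooling choice.
#' No multiple-testing correction is applied by default, matching the
#' screening procedure this reproduces; `adjust = "BH"` applies
#' Benjamini–Hochberg to the p-values before selection.
#'
#' @param features Labeled feature tibble with a `class_id` column (1/2/3)
#'   and the feature columns; a `subject` column is required for
#'   `unit = "subject"`.
#' @param feature_names Columns to screen (default: all 30 HRV features
#'   present).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param unit `"window"` (pool windows, default) or `"subject"`.
#' @return Tibble with one row per feature (columns as in
#'   [group_comparison()]), ordered as given; see [select_features()] for the
#'   ranked selection.
#' @export
screen_features <- function(features, feature_names = NULL, alpha = 0.05,
                            adjust = c("none", "BH"),
                            unit = c("window", "subject")) {
  adjust <- match.arg(adjust)
  unit <- match.arg(unit)
  if (is.null(feature_names))
    feature_names <- intersect(hrv_feature_names(), names(features))
  dat <- features[!is.na(features$class_id), ]
  if (unit == "subject") {
    if (is.null(dat$subject)) abort("`unit = \"subject\"` needs a `subject` column")
    dat <- dat |>
      dplyr::group_by(.data$subject, .data$class_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(feature_names),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  flags <- normality_flags(dat, feature_names, alpha = alpha)
  res <- purrr::map_dfr(feature_names, function(nm) {
    group_comparison(dat[[nm]], dat$class_id,
                     normal = flags$normal[flags$feature == nm],
                     feature = nm, alpha = alpha)
  })
  if (adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
    res$selected <- res$p_value < alpha
  }
  res
}

#' Rank and select screened features
#'
#' @param results Screening tibble from [screen_features()].
#' @param alpha Selection threshold (default 0.05).
#' @return Character vector of selected feature names, p-value ascending.
#' @examples
#' \donttest{
#' # select_features(screen_features(labeled), alpha = 0.05)
#' }
#' @export
select_features <- function(results, alpha = 0.05) {
  sel <- results[results$p_value < alpha, ]
  sel$feature[order(sel$p_value)]
}
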