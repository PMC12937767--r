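# Evaluation: confusion matrix, macro metric battery, bootstrap confidence
# intervals and plotting.
#
# Per-class precision/recall/specificity are one-vs-rest; macro metrics are
# unweighted class means; F1 is macro-F1; the multiclass Matthews
# correlation uses the Gorodkin generalization over the full confusion
# matrix; Cohen's kappa is (p_o - p_e) / (1 - p_e) with chance agreement
# from the marginals.

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param label_order Class ordering for rows/columns.
#'   Default sorted union of observed labels.
#' @return Integer matrix, rows = true class, columns = predicted class,
#'   class `lesion_confusion`.
#' @export
confusion <- function(y_true, y_pred, label_order = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length")
  }
  if (is.null(label_order)) label_order <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% label_order)) {
    abort("labels outside `label_order`")
  }
  cm <- table(factor(y_true, levels = label_order),
              factor(y_pred, levels = label_order))
  out <- matrix(as.integer(cm), nrow(cm), ncol(cm),
                dimnames = list(true = label_order, pred = label_order))
  class(out) <- c("lesion_confusion", class(out))
  out
}

# Gorodkin multiclass Matthews correlation from a confusion matrix.
mcc_multiclass <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  tr <- sum(diag(cm))
  rows <- rowSums(cm); cols <- colSums(cm)
  num <- tr * n - sum(rows * cols)
  den <- sqrt(n^2 - sum(cols^2)) * sqrt(n^2 - sum(rows^2))
  if (den == 0) return(0)
  num / den
}

# Macro one-vs-rest ROC AUC from a probability matrix.
macro_auc <- function(y_true, probs, label_order) {
  aucs <- vapply(seq_along(label_order), function(k) {
    pos <- y_true == label_order[k]
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(
      response = factor(pos, levels = c(FALSE, TRUE)),
      predictor = probs[, k], quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE)
    ))
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Classification metric battery
#'
#' Accuracy, macro precision / recall / F1 / one-vs-rest specificity,
#' multiclass Matthews correlation, Cohen's kappa, per-class rates, and
#' macro one-vs-rest AUC when class probabilities are supplied. A class that
#' is never predicted gets precision 0 with a warning.
#'
#' @param cm A `lesion_confusion` matrix from [confusion()].
#' @param probs Optional probability matrix (rows aligned with the samples
#'   that produced `cm` is not required; supply `y_true` too).
#' @param y_true Optional label vector matching `probs` rows, needed for AUC.
#' @return Object of class `lesion_metrics`.
#' @export
compute_metrics <- function(cm, probs = NULL, y_true = NULL) {
  if (!inherits(cm, "lesion_confusion")) {
    abort("`cm` must come from confusion()")
  }
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) abort("confusion matrix is empty")
  labels <- rownames(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- n - tp - fn - fp

  if (any(tp + fp == 0)) {
    warn(sprintf("class(es) never predicted (%s): precision set to 0",
                 paste(labels[tp + fp == 0], collapse = ", ")))
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)

  p_o <- sum(tp) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1

  auc <- if (!is.null(probs) && !is.null(y_true)) {
    macro_auc(as.character(y_true), probs, labels)
  } else NA_real_

  structure(list(
    confusion = cm,
    n = n,
    accuracy = p_o,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    macro_specificity = mean(specificity),
    macro_auc = auc,
    mcc = mcc_multiclass(m),
    kappa = kappa,
    per_class = tibble::tibble(
      class = labels,
      support = as.integer(rowSums(m)),
      precision = unname(precision),
      recall = unname(recall),
      specificity = unname(specificity),
      f1 = unname(f1)
    )
  ), class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf(
    "<lesion_metrics> n = %d | acc %.4f | macro-F1 %.4f | kappa %.4f | MCC %.4f\n",
    x$n, x$accuracy, x$macro_f1, x$kappa, x$mcc))
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname compute_metrics
#' @param x A `lesion_metrics` object.
#' @param ... Unused.
#' @method tidy lesion_metrics
#' @export
tidy.lesion_metrics <- function(x, ...) x$per_class

#' One-row summary of a metric battery
#'
#' @param x A `lesion_metrics` object.
#' @param ... Unused.
#' @method glance lesion_metrics
#' @export
glance.lesion_metrics <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = x$accuracy,
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    macro_specificity = x$macro_specificity,
    macro_auc = x$macro_auc,
    mcc = x$mcc,
    kappa = x$kappa
  )
}

#' Bootstrap confidence interval for a classification metric
#'
#' Percentile interval from `B` resamples (with replacement) of the
#' prediction/label pairs. Degenerate resamples fall back to the metric
#' battery's own conventions (e.g. precision 0 for never-predicted classes).
#'
#' @param y_true,y_pred Label vectors.
#' @param probs Optional probability matrix (needed for `"macro_auc"`).
#' @param metric Name of a scalar field of [compute_metrics()] output,
#'   e.g. `"accuracy"`, `"macro_f1"`, `"kappa"`, `"mcc"`.
#' @param B Number of bootstrap resamples. Default 1000.
#' @param level Interval coverage. Default 0.95.
#' @param seed Integer seed.
#' @param label_order Class ordering.
#' @return Tibble with `metric`, `estimate`, `lower`, `upper`, `B`, `level`.
#' @export
bootstrap_ci <- function(y_true, y_pred, probs = NULL, metric = "accuracy",
                         B = 1000L, level = 0.95, seed = 1L,
                         label_order = NULL) {
  if (B < 100) abort("`B` must be at least 100")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(label_order)) label_order <- sort(unique(c(y_true, y_pred)))
  metric_of <- function(idx) {
    cm <- confusion(y_true[idx], y_pred[idx], label_order)
    rep_metrics <- suppressWarnings(compute_metrics(
      cm,
      probs = if (!is.null(probs)) probs[idx, , drop = FALSE],
      y_true = if (!is.null(probs)) y_true[idx]
    ))
    rep_metrics[[metric]]
  }
  estimate <- metric_of(seq_along(y_true))
  n <- length(y_true)
  draws <- with_seed(derive_seed(seed, "bootstrap", metric), {
    vapply(seq_len(B), function(b) metric_of(sample.int(n, n, replace = TRUE)),
           0)
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(metric = metric, estimate = estimate,
                 lower = qs[1], upper = qs[2], B = as.integer(B),
                 level = level)
}

#' Heat-map of a confusion matrix
#'
#' @param object A `lesion_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lesion_confusion
#' @export
autoplot.lesion_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "pred", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-class metrics
#'
#' @param object A `lesion_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lesion_metrics
#' @export
autoplot.lesion_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
                              cols = c("precision", "recall", "specificity", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of top ensemble feature importances
#'
#' @param object A `lesion_ensemble`.
#' @param top_n Number of features to show. Default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lesion_ensemble
#' @export
autoplot.lesion_ensemble <- function(object, top_n = 20L, ...) {
  imp <- utils::head(feature_importance(object), top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$gain),
    y = .data$gain, fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean gain", fill = "block") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
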