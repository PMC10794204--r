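#' Overall classification accuracy
#'
#' Fraction of exact label matches, `sum(y == y_pred) / n`.
#'
#' @param y_true,y_pred Equal-length integer vectors of labels.
#' @return Accuracy in `[0,1]`.
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop("y_true and y_pred must be equal-length, non-empty", call. = FALSE)
  mean(y_true == y_pred)
}

#' Three-class confusion matrix
#'
#' Counts with rows = true class and columns = predicted class
#' (0 = small, 1 = normal, 2 = large).
#'
#' @param y_true,y_pred Label vectors with values in `{0, 1, 2}`.
#' @return An object of class `vhs_confusion`: `counts` (3 x 3) and `n`.
#' @export
vhs_confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch", call. = FALSE)
  if (!all(y_true %in% 0:2) || !all(y_pred %in% 0:2))
    stop("labels must be in {0, 1, 2}", call. = FALSE)
  lab <- vhs_class_labels()
  counts <- table(factor(y_true, levels = 0:2, labels = lab),
                  factor(y_pred, levels = 0:2, labels = lab))
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(true = lab, predicted = lab))
  structure(list(counts = counts, n = length(y_true)),
            class = "vhs_confusion")
}

#' Confusion-matrix percentage conventions
#'
#' For each cell, the share of the whole dataset (`count/n`); for each
#' true-class row, the correctly predicted share (diagonal over row sum)
#' and the per-cell error shares (off-diagonal over row sum). All values
#' are percentages rounded to one decimal, the convention used when
#' annotating confusion matrices (e.g. 30 of 33 small hearts predicted
#' small: row-correct 90.9%; 30 of 200 images: 15.0% of the total).
#'
#' @param cm A [vhs_confusion()].
#' @return List with `cell_pct` (3 x 3), `row_correct_pct` (length 3),
#'   `row_pct` (3 x 3 row-normalized; off-diagonal entries are the error
#'   percentages).
#' @export
confusion_percentages <- function(cm) {
  stopifnot(inherits(cm, "vhs_confusion"))
  counts <- cm$counts
  rs <- rowSums(counts)
  row_pct <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  list(cell_pct = round(counts / cm$n * 100, 1),
       row_correct_pct = round(diag(row_pct), 1),
       row_pct = round(row_pct, 1))
}

#' @export
print.vhs_confusion <- function(x, ...) {
  cat("<vhs_confusion> n =", x$n, "\n")
  print(x$counts)
  pc <- confusion_percentages(x)
  cat("per-class accuracy (%):",
      paste(sprintf("%s %.1f", rownames(x$counts), pc$row_correct_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' One-vs-rest AUC, precision, specificity and sensitivity per class
#'
#' For each class k the labels are binarized (k against the rest). AUC is
#' the rank statistic on the class-k probability (probability that a
#' random positive scores above a random negative, ties counted one
#' half). Precision, specificity and sensitivity are computed from the
#' argmax decision rule: TP/(TP+FP), TN/(TN+FP) and TP/(TP+FN). A class
#' absent from `y_true` yields `NA` metrics rather than zeros.
#'
#' @param y_true Integer labels 0..2.
#' @param class_probs n x 3 matrix of class probabilities (rows sum to 1).
#' @return A tibble with one row per class.
#' @export
one_vs_rest_metrics <- function(y_true, class_probs) {
  class_probs <- as.matrix(class_probs)
  stopifnot(length(y_true) == nrow(class_probs), ncol(class_probs) == 3L)
  if (any(abs(rowSums(class_probs) - 1) > 1e-6))
    stop("class_probs rows must sum to 1", call. = FALSE)
  y_hat <- max.col(class_probs) - 1L
  purrr::map_dfr(0:2, function(k) {
    pos <- y_true == k
    n1 <- sum(pos)
    n0 <- sum(!pos)
    auc <- if (n1 == 0L || n0 == 0L) {
      NA_real_
    } else {
      r <- rank(class_probs[, k + 1L])        # midranks handle ties
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    tp <- sum(y_hat == k & pos)
    fp <- sum(y_hat == k & !pos)
    fn <- sum(y_hat != k & pos)
    tn <- sum(y_hat != k & !pos)
    div <- function(a, b) if (b == 0) NA_real_ else a / b
    tibble::tibble(class = k, class_name = vhs_class_labels()[k + 1L],
                   n = n1, auc = auc,
                   precision = div(tp, tp + fp),
                   specificity = div(tn, tn + fp),
                   sensitivity = div(tp, tp + fn))
  })
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for
#' paired continuous ratings (e.g. the flattened keypoint coordinates
#' placed by two annotators). Computed from the standard mean-squares
#' decomposition; symmetric in its arguments.
#'
#' @param ratings_a,ratings_b Equal-length numeric vectors (n >= 2).
#' @return Scalar in `[-1, 1]`.
#' @export
icc_agreement <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("ratings must be paired (equal length)", call. = FALSE)
  n <- length(ratings_a)
  if (n < 2L) stop("need at least 2 paired ratings", call. = FALSE)
  x <- cbind(as.numeric(ratings_a), as.numeric(ratings_b))
  k <- 2L
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Full evaluation report
#'
#' Bundles overall accuracy, the confusion matrix with its percentage
#' conventions, and per-class one-vs-rest metrics; optionally ICC between
#' two annotators' measurements.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_probs Optional n x 3 probability matrix (enables AUC).
#' @param icc Optional list(a =, b =) of paired continuous ratings.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred, class_probs = NULL, icc = NULL) {
  cm <- vhs_confusion(y_true, y_pred)
  per_class <- if (!is.null(class_probs)) {
    one_vs_rest_metrics(y_true, class_probs)
  } else {
    NULL
  }
  icc_val <- if (!is.null(icc)) icc_agreement(icc$a, icc$b) else NA_real_
  structure(list(overall_accuracy = overall_accuracy(y_true, y_pred),
                 confusion = cm,
                 percentages = confusion_percentages(cm),
                 per_class = per_class,
                 icc = icc_val, icc_form = "ICC(2,1) absolute agreement"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.3f (n = %d)\n",
              x$overall_accuracy, x$confusion$n))
  print(x$confusion$counts)
  if (!is.null(x$per_class)) {
    cat("\nper-class one-vs-rest metrics:\n")
    print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  }
  if (!is.na(x$icc))
    cat(sprintf("\n%s: %.3f\n", x$icc_form, x$icc))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A [metrics_report()].
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(overall_accuracy = report$overall_accuracy,
              n = report$confusion$n,
              confusion_counts = report$confusion$counts,
              cell_pct = report$percentages$cell_pct,
              row_correct_pct = report$percentages$row_correct_pct,
              per_class = report$per_class,
              icc = if (is.na(report$icc)) NULL else report$icc,
              icc_form = report$icc_form)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Confusion-matrix plot
#'
#' Tiles with ground truth on the x-axis and predictions on the y-axis;
#' each cell shows the count and its share of all samples, with the
#' row-normalized correct (diagonal) and error (off-diagonal) percentages.
#'
#' @param object A `vhs_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vhs_confusion <- function(object, ...) {
  pc <- confusion_percentages(object)
  lab <- vhs_class_labels()
  df <- tidyr::expand_grid(true = factor(lab, levels = lab),
                           predicted = factor(lab, levels = lab))
  df$count <- as.vector(t(object$counts))    # rows of counts = true class
  df$cell_pct <- as.vector(t(pc$cell_pct))
  df$row_pct <- as.vector(t(pc$row_pct))
  df$diag <- df$true == df$predicted
  df$label <- sprintf("%d\n%.1f%% of all\n%.1f%% of row",
                      df$count, df$cell_pct, df$row_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    colour = .data$diag), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "ground truth", y = "predicted") +
    ggplot2::theme_minimal()
}
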