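#' Multiclass confusion matrix
#'
#' Rows are the observed (ground-truth) classes, columns the predicted
#' classes. Cells may be instance counts or percentages of the total; all
#' derived metrics are ratios and identical under either unit.
#'
#' @param cells Square non-negative numeric matrix with matching row and
#'   column names (or unnamed; then `class_names` is required).
#' @param unit `"count"` or `"percent"` (percent cells must total ~100).
#' @param class_names Optional class names overriding dimnames.
#' @return Object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(cells, unit = c("count", "percent"),
                             class_names = NULL) {
  unit <- match.arg(unit)
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells)) stop("confusion matrix must be square")
  if (any(cells < 0)) stop("confusion matrix cells must be non-negative")
  if (!is.null(class_names)) {
    if (length(class_names) != nrow(cells))
      stop("'class_names' length must match the matrix dimension")
    dimnames(cells) <- list(class_names, class_names)
  }
  if (is.null(rownames(cells)))
    stop("confusion matrix needs class names (dimnames or 'class_names')")
  if (!identical(rownames(cells), colnames(cells)))
    stop("row and column class names must match")
  tot <- sum(cells)
  if (tot <= 0) stop("confusion matrix total is zero")
  if (unit == "percent" && abs(tot - 100) > 0.5)
    stop("percent-unit matrix must total ~100, got ", tot)
  structure(list(cells = cells, unit = unit,
                 class_names = rownames(cells)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = observed, columns = predicted; unit: ",
      x$unit, ")\n", sep = "")
  print(x$cells)
  invisible(x)
}

#' Per-class and overall classification metrics
#'
#' For each class c, with TP the diagonal cell, FN the rest of its row,
#' FP the rest of its column and TN the remainder of the matrix:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F-score their harmonic
#' mean, specificity = TN/(TN+FP); overall accuracy = trace/total. A class
#' with an empty row or column has the affected metrics undefined; they
#' are reported as `NA` with a warning and excluded from the macro
#' averages (which are computed from unrounded per-class values).
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `"metrics_report"`: `per_class` data frame
#'   (precision, recall, f_score, specificity), `overall_accuracy`,
#'   `macro` (named vector of macro averages).
#' @export
confusion_to_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$cells
  tot <- sum(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- tot - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f_score <- ifelse(!is.na(precision) & !is.na(recall) &
                      (precision + recall) > 0,
                    2 * precision * recall / (precision + recall), NA_real_)
  specificity <- safe(tn, tn + fp)
  per_class <- data.frame(precision = precision, recall = recall,
                          f_score = f_score, specificity = specificity,
                          row.names = cm$class_names)
  if (anyNA(per_class))
    warning("empty class row/column: affected metrics reported as NA")
  structure(list(per_class = per_class,
                 overall_accuracy = sum(tp) / tot,
                 macro = colMeans(per_class, na.rm = TRUE),
                 class_names = cm$class_names),
            class = "metrics_report")
}

#' Overall accuracy of a confusion matrix
#'
#' Trace divided by grand total: the fraction of correct classifications
#' across all behaviours.
#'
#' @param cm A `confusion_matrix`.
#' @return Real in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sum(diag(cm$cells)) / sum(cm$cells)
}

# round-half-up at `digits` decimals (R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a metrics report for display
#'
#' Renders per-class precision, recall, F-score and specificity plus the
#' overall accuracy, by default as integer percentages under deterministic
#' round-half-up (96.5 always prints as "97\%", never banker's rounding).
#' Full precision is retained in the report object.
#'
#' @param r A `metrics_report`.
#' @param digits Decimal digits of the rendered percentage (default 0).
#' @return Character matrix, one row per class plus an overall row.
#' @export
format_report <- function(r, digits = 0) {
  stopifnot(inherits(r, "metrics_report"))
  fmt <- function(v) ifelse(is.na(v), "-",
    paste0(formatC(round_half_up(100 * v, digits),
                   format = "f", digits = digits), "%"))
  m <- apply(as.matrix(r$per_class), c(1, 2), fmt)
  colnames(m) <- c("Precision", "Recall", "F-score", "Specificity")
  rbind(m, Overall = c(fmt(r$overall_accuracy), "", "", ""))
}

#' @export
print.metrics_report <- function(x, digits = 0, ...) {
  print(format_report(x, digits), quote = FALSE)
  invisible(x)
}

#' @rdname sensor_io
#' @param unit Cell unit of the confusion CSV, `"count"` or `"percent"`.
#' @export
read_confusion_csv <- function(file, unit = c("count", "percent")) {
  d <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  confusion_matrix(as.matrix(d), unit = match.arg(unit))
}
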