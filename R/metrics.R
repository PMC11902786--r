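#' Confusion matrix from 0-based labels
#'
#' Builds the `C x C` integer count table with rows indexing the true class
#' and columns the predicted class. All downstream metrics (overall accuracy,
#' average accuracy, Cohen's kappa) consume this table, never raw label
#' vectors, so the arithmetic stays exact up to the final divisions.
#'
#' @param y_true,y_pred Integer vectors of equal length with values in
#'   `[0, n_classes)`.
#' @param n_classes Number of classes C.
#' @return Integer matrix `[C x C]` of class `confusion_matrix`;
#'   `counts[i, j]` is the number of samples of true class `i - 1` predicted
#'   as class `j - 1`.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(1, 1, 1), n_classes = 2)
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  if (length(y_true) < 1) stop("no samples", call. = FALSE)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  C <- as.integer(n_classes)
  if (any(y_true < 0L | y_true >= C) || any(y_pred < 0L | y_pred >= C)) {
    stop(sprintf("labels must lie in [0, %d)", C), call. = FALSE)
  }
  cm <- matrix(0L, C, C,
               dimnames = list(true = as.character(seq_len(C) - 1L),
                               predicted = as.character(seq_len(C) - 1L)))
  tab <- table(factor(y_true, levels = 0:(C - 1L)),
               factor(y_pred, levels = 0:(C - 1L)))
  cm[] <- as.integer(tab)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

.check_cm <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative", call. = FALSE)
  if (sum(cm) <= 0) stop("empty confusion matrix", call. = FALSE)
  cm
}

#' Overall accuracy
#'
#' The proportion of correctly classified samples among all samples:
#' `OA = sum_i TP_i / sum_i Total_i`, with `TP_i` the diagonal counts and
#' `Total_i` the row sums of the confusion matrix.
#'
#' @param cm A square count matrix (see [confusion_matrix()]).
#' @return A number in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  cm <- .check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Average (per-class mean) accuracy
#'
#' The unweighted mean of the per-class accuracies
#' `AA = (1/C) sum_i TP_i / Total_i`. Undefined when a class has no true
#' samples; such matrices are rejected — drop empty classes explicitly if
#' that is intended.
#'
#' @inheritParams overall_accuracy
#' @return A number in `[0, 1]`.
#' @export
average_accuracy <- function(cm) {
  cm <- .check_cm(cm)
  totals <- rowSums(cm)
  if (any(totals == 0)) {
    stop("average_accuracy undefined: some class has zero true samples",
         call. = FALSE)
  }
  mean(diag(cm) / totals)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)` where `Po` is the
#' overall accuracy and `Pe = sum_i row_i * col_i / n^2` is the expected
#' agreement from the marginals.
#'
#' @inheritParams overall_accuracy
#' @return A number in `(-Inf, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- .check_cm(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    stop("kappa undefined: expected agreement Pe = 1 (degenerate matrix)",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' All classification metrics for a confusion matrix
#'
#' Computes overall accuracy, average accuracy, Cohen's kappa, the per-class
#' accuracies, and the observed/expected agreements in one pass.
#'
#' @inheritParams overall_accuracy
#' @return A list of class `metrics_report` with elements `OA`, `AA`,
#'   `Kappa`, `per_class_accuracy`, `Po`, `Pe`, and the input matrix `cm`.
#' @export
#' @examples
#' metrics_report(matrix(c(8, 3, 2, 7), 2, 2))
metrics_report <- function(cm) {
  m <- .check_cm(cm)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  totals <- rowSums(m)
  per_class <- ifelse(totals > 0, diag(m) / totals, NA_real_)
  structure(list(
    OA = po,
    AA = if (any(totals == 0)) NA_real_ else mean(per_class),
    Kappa = if (pe >= 1) NA_real_ else (po - pe) / (1 - pe),
    per_class_accuracy = per_class,
    Po = po, Pe = pe,
    cm = m
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  # percentages shown with 2 decimals; stored values stay full precision
  cat(sprintf("OA = %.2f%%  AA = %.2f%%  Kappa = %.4f\n",
              100 * x$OA, 100 * x$AA, x$Kappa))
  cat("per-class accuracy (%):",
      paste(sprintf("%.2f", 100 * x$per_class_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    class = seq_along(x$per_class_accuracy) - 1L,
    accuracy = x$per_class_accuracy
  )
}

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(OA = x$OA, AA = x$AA, Kappa = x$Kappa, Po = x$Po, Pe = x$Pe,
                 n = sum(x$cm))
}

#' Serialize a metrics report to a flat JSON document
#' @param x A `metrics_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  stopifnot(inherits(x, "metrics_report"))
  doc <- list(OA = x$OA, AA = x$AA, Kappa = x$Kappa, Po = x$Po, Pe = x$Pe,
              per_class_accuracy = x$per_class_accuracy)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a confusion matrix as CSV
#' @param cm A confusion matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  write.csv(as.data.frame(unclass(as.matrix(cm))), path, row.names = TRUE)
  invisible(path)
}
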