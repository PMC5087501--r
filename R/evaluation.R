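# Evaluation: K x K confusion matrices (rows = true label, columns =
# predicted), per-class precision / recall / F1 with macro averaging, and
# leave-one-subject-out cross validation with fold-summed confusion
# matrices.

#' Confusion matrix of a prediction
#'
#' `counts[i, j]` is the number of segments with true label `i` predicted
#' as label `j`.
#'
#' @param truth,prediction Equal-length label vectors.
#' @param labels Label order of the matrix; defaults to the sorted union.
#'   A value outside `labels` is an error.
#' @return Integer matrix classed `"confusion_matrix"`, rows = true.
#' @export
confusion_matrix <- function(truth, prediction, labels = NULL) {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    abort("`truth` and `prediction` must have equal length")
  }
  labels <- labels %||% sort(unique(c(truth, prediction)))
  unknown <- setdiff(unique(c(truth, prediction)), labels)
  if (length(unknown)) {
    abort(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  cm <- table(factor(truth, levels = labels),
              factor(prediction, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(true = labels, predicted = labels))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain count matrix to a confusion matrix
#'
#' @param x Square non-negative count matrix, rows = true labels.
#' @param labels Optional label order; defaults to the row names.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) abort("a confusion matrix must be square")
  if (any(x < 0)) abort("confusion counts must be non-negative")
  labels <- labels %||% rownames(x) %||% paste0("class_", seq_len(nrow(x)))
  dimnames(x) <- list(true = labels, predicted = labels)
  structure(x, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. A class never
#' predicted has precision 0 (flagged in `empty_prediction`); `F1` is 0
#' by convention when precision + recall is 0. The macro F1 is the
#' unweighted mean of the per-class F1 values.
#'
#' @param cm A `confusion_matrix` (or square count matrix).
#' @return Tibble `class, support, precision, recall, f1,
#'   empty_prediction` with the macro F1 in attribute `macro_f1` (see
#'   [macro_f1()]).
#' @export
class_metrics <- function(cm) {
  cm <- as_confusion_matrix(cm)
  if (nrow(cm) < 2) abort("metrics need at least 2 classes")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  predicted <- tp + fp
  precision <- ifelse(predicted == 0, 0, tp / pmax(predicted, 1))
  recall <- ifelse(tp + fn == 0, 0, tp / pmax(tp + fn, 1))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  out <- tibble(
    class = rownames(cm),
    support = as.integer(rowSums(cm)),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    empty_prediction = predicted == 0
  )
  structure(out, macro_f1 = mean(f1))
}

#' Macro-averaged F1
#'
#' Unweighted mean of the per-class F1 values.
#'
#' @param x A `confusion_matrix` or the output of [class_metrics()].
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(x) {
  if (is.matrix(x)) x <- class_metrics(x)
  mf <- attr(x, "macro_f1")
  mf %||% mean(x$f1)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "count")) |>
    dplyr::rename(truth = "true", prediction = "predicted") |>
    dplyr::mutate(truth = as.character(.data$truth),
                  prediction = as.character(.data$prediction))
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  metrics <- class_metrics(x)
  tibble(n = sum(x), accuracy = sum(diag(unclass(x))) / sum(x),
         macro_f1 = macro_f1(metrics))
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted label", y = "true label")
}

#' Leave-one-subject-out cross validation
#'
#' Holds out each subject in turn, trains on the remaining subjects via
#' `fit`, predicts the held-out rows via `predict_fn`, and sums the
#' per-fold confusion matrices.
#'
#' @param data Tibble with one row per segment; must contain the subject
#'   and label columns.
#' @param fit Function `function(train_data) -> model`.
#' @param predict_fn Function `function(model, test_data) -> labels`.
#' @param subject_col,label_col Column names. Defaults `"subject"`,
#'   `"label"`.
#' @param labels Label order for the summed matrix; defaults to the
#'   sorted labels present.
#' @return A `loso_result`: list with `confusion` (summed
#'   `confusion_matrix`), `metrics` (per-class tibble), `macro_f1`, and a
#'   per-fold `folds` tibble.
#' @export
loso_cv <- function(data, fit, predict_fn, subject_col = "subject",
                    label_col = "label", labels = NULL) {
  data <- as_tibble(data)
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 2) {
    abort("leave-one-subject-out needs at least 2 subjects")
  }
  labels <- labels %||% sort(unique(as.character(data[[label_col]])))
  total <- matrix(0L, length(labels), length(labels),
                  dimnames = list(true = labels, predicted = labels))
  folds <- list()
  for (subject in subjects) {
    test <- data[[subject_col]] == subject
    if (!any(test)) {
      warn(sprintf("subject `%s` has no data; skipped", subject))
      next
    }
    model <- fit(data[!test, , drop = FALSE])
    pred <- predict_fn(model, data[test, , drop = FALSE])
    cm <- confusion_matrix(data[[label_col]][test], pred, labels)
    total <- total + unclass(cm)
    folds[[length(folds) + 1]] <- tibble(
      subject = subject, n = sum(test),
      accuracy = sum(diag(unclass(cm))) / sum(cm)
    )
  }
  confusion <- as_confusion_matrix(total, labels)
  metrics <- class_metrics(confusion)
  structure(
    list(confusion = confusion, metrics = metrics,
         macro_f1 = macro_f1(metrics), folds = dplyr::bind_rows(folds)),
    class = "loso_result"
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d fold(s), macro F1 = %.3f\n",
              nrow(x$folds), x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.loso_result <- function(x, ...) x$metrics

#' @export
glance.loso_result <- function(x, ...) {
  tibble(n = sum(x$confusion), folds = nrow(x$folds),
         accuracy = sum(diag(unclass(x$confusion))) / sum(x$confusion),
         macro_f1 = x$macro_f1)
}
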