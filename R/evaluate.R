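# Confusion matrices, accuracy, per-class sensitivity, and the cross-model
# comparison table.

#' Confusion matrix
#'
#' @param true_labels,predicted_labels Equal-length integer vectors with
#'   values in `0..n_classes-1`.
#' @param n_classes Number of classes K.
#' @return K x K integer matrix; rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_parameter("Label vectors must have equal length.")
  }
  labs <- c(true_labels, predicted_labels)
  if (any(labs < 0) || any(labs >= n_classes) || any(labs != round(labs))) {
    stop_parameter(sprintf("Labels must be integers in 0..%d.", n_classes - 1))
  }
  lv <- 0:(n_classes - 1)
  m <- table(factor(true_labels, levels = lv),
             factor(predicted_labels, levels = lv))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Overall accuracy from a confusion matrix
#' @param confusion K x K confusion matrix (rows = true class).
#' @return Proportion correct (trace / total).
#' @export
accuracy <- function(confusion) {
  if (is.null(dim(confusion)) || sum(confusion) == 0) {
    stop_parameter("Confusion matrix is empty.")
  }
  sum(diag(confusion)) / sum(confusion)
}

#' Per-class sensitivity (recall) from a confusion matrix
#'
#' `sensitivity[k] = confusion[k, k] / rowsum k`. Classes absent from the
#' test set get sensitivity 0 and are flagged in the `"undefined"` attribute.
#'
#' @inheritParams accuracy
#' @return Numeric vector of length K, with attribute `undefined` listing
#'   (0-based) classes whose row is empty.
#' @export
sensitivity <- function(confusion) {
  if (is.null(dim(confusion)) || sum(confusion) == 0) {
    stop_parameter("Confusion matrix is empty.")
  }
  rs <- rowSums(confusion)
  s <- ifelse(rs > 0, diag(confusion) / rs, 0)
  undef <- which(rs == 0) - 1L
  if (length(undef)) {
    warn(sprintf("Sensitivity undefined for empty true class(es): %s.",
                 paste(undef, collapse = ", ")))
    attr(s, "undefined") <- undef
  }
  s
}

#' Assemble the cross-model comparison table
#'
#' One row per (method, image dimension, image kind) combination: epoch at
#' which the run stopped, minimum cross-entropy loss, train accuracy, test
#' accuracy, elapsed seconds. A complete pipeline run over the SVM plus both
#' CNNs on all seven image kinds yields exactly 15 rows.
#'
#' @param results List of entries, each a list with `method`, `dimension`,
#'   `image_kind` and a `fit` (`cnn_fit` or `svm_fit`).
#' @return A tibble of class `comparison_table`, sorted by descending test
#'   accuracy (stable on ties).
#' @export
build_comparison <- function(results) {
  rows <- lapply(results, function(r) {
    fit <- r$fit
    if (inherits(fit, "cnn_fit")) {
      tibble(
        method = r$method, dimension = r$dimension, image_kind = r$image_kind,
        epoch = fit$stopping_epoch, loss = fit$min_loss,
        train_accuracy = fit$train_accuracy, test_accuracy = fit$accuracy,
        elapsed = fit$elapsed
      )
    } else if (inherits(fit, "svm_fit")) {
      tibble(
        method = r$method, dimension = r$dimension, image_kind = r$image_kind,
        epoch = NA_integer_, loss = NA_real_,
        train_accuracy = if (is.na(fit$cv_accuracy)) fit$train_accuracy
                         else fit$cv_accuracy,
        test_accuracy = fit$accuracy, elapsed = fit$elapsed
      )
    } else {
      stop_parameter("Each result needs a cnn_fit or svm_fit under `fit`.")
    }
  })
  out <- dplyr::bind_rows(rows)
  key <- paste(out$method, out$dimension, out$image_kind)
  if (anyDuplicated(key)) {
    stop_parameter(sprintf("Duplicate comparison row: %s.", key[duplicated(key)][1]))
  }
  out <- out[order(-out$test_accuracy), ]
  class(out) <- unique(c("comparison_table", class(out)))
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("# Model comparison (%d rows)\n", nrow(x)))
  NextMethod()
}
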