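# Radial-basis SVM with c/g grid search (libsvm via e1071).

#' Grid search for SVM hyperparameters
#'
#' Exhaustive evaluation of a (cost, gamma) grid by k-fold cross-validated
#' accuracy on the training spectra. Folds are deterministic (stratified
#' round-robin by class, in row order). Ties break to the smaller cost, then
#' the smaller gamma. The default log2-spaced grid spans c in 2^-5..2^21 and
#' g in 2^-15..2^3.
#'
#' @param x N x d numeric matrix of training spectra.
#' @param y Integer class labels (0-based) of length N.
#' @param c_grid,g_grid Positive cost / gamma grids.
#' @param folds Number of cross-validation folds (2 <= folds <= N).
#' @return List: `best_c`, `best_g`, `cv_accuracy`, and the full `grid`
#'   tibble of CV accuracies.
#' @export
svm_grid_search <- function(x, y,
                            c_grid = 2^seq(-5, 21, by = 2),
                            g_grid = 2^seq(-15, 3, by = 2),
                            folds = 5L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) {
    stop_parameter("Training data must contain at least two classes.")
  }
  if (length(c_grid) < 1 || length(g_grid) < 1 ||
      any(c_grid <= 0) || any(g_grid <= 0)) {
    stop_parameter("Grids must be non-empty and positive.")
  }
  N <- nrow(x)
  if (folds < 2 || folds > N) stop_parameter("`folds` must satisfy 2 <= folds <= N.")
  yf <- factor(y)
  # stratified round-robin: the i-th member of each class goes to fold
  # ((i - 1) mod folds) + 1; deterministic in row order
  fold <- integer(N)
  for (lv in levels(yf)) {
    idx <- which(yf == lv)
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }

  cv_acc <- function(cost, gamma) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(yf[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    correct / N
  }

  grid <- tidyr::expand_grid(cost = sort(unique(c_grid)),
                             gamma = sort(unique(g_grid)))
  grid$cv_accuracy <- NA_real_
  best <- list(acc = -Inf, c = NA_real_, g = NA_real_)
  for (i in seq_len(nrow(grid))) {
    a <- cv_acc(grid$cost[i], grid$gamma[i])
    grid$cv_accuracy[i] <- a
    if (a > best$acc) { # iteration order (c asc, g asc) enforces tie-breaks
      best <- list(acc = a, c = grid$cost[i], g = grid$gamma[i])
    }
  }
  list(best_c = best$c, best_g = best$g, cv_accuracy = best$acc, grid = grid)
}

#' Fit and evaluate the SVM at chosen hyperparameters
#'
#' @param x_train,x_test Spectra matrices.
#' @param y_train,y_test Integer labels (0-based).
#' @param cost,gamma RBF hyperparameters (e.g. from [svm_grid_search()]).
#' @param cv_accuracy Optional grid-search CV accuracy to carry along.
#' @return An `svm_fit`: model, confusion matrix, train/test accuracy,
#'   per-class sensitivity, elapsed seconds.
#' @export
svm_train_eval <- function(x_train, y_train, x_test, y_test, cost, gamma,
                           cv_accuracy = NA_real_) {
  t0 <- proc.time()[["elapsed"]]
  K <- length(unique(c(y_train, y_test)))
  lv <- factor(y_train, levels = sort(unique(c(y_train, y_test))))
  fit <- e1071::svm(as.matrix(x_train), lv, kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  pred_test <- as.integer(as.character(predict(fit, as.matrix(x_test))))
  pred_train <- as.integer(as.character(predict(fit, as.matrix(x_train))))
  confusion <- confusion_matrix(y_test, pred_test, K)
  structure(
    list(
      model = fit, cost = cost, gamma = gamma, cv_accuracy = cv_accuracy,
      confusion = confusion,
      train_accuracy = mean(pred_train == y_train),
      accuracy = accuracy(confusion),
      sensitivity = sensitivity(confusion),
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "svm_fit"
  )
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit: cost %g, gamma %g, test accuracy %.3f>\n",
              x$cost, x$gamma, x$accuracy))
  invisible(x)
}

#' @rdname glance.cnn_fit
#' @export
glance.svm_fit <- function(x, ...) {
  tibble(
    cost = x$cost, gamma = x$gamma, cv_accuracy = x$cv_accuracy,
    train_accuracy = x$train_accuracy, test_accuracy = x$accuracy,
    elapsed = x$elapsed
  )
}
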