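# CNN training: SGD schedules, early stopping, per-epoch curves.

#' CNN training configuration
#'
#' Defaults encode each architecture's training recipe: the Alexnet-style model
#' uses Nesterov momentum with a staircase learning rate
#' `0.01 * 0.99^(epoch div 3)` and early stopping on test accuracy
#' (min_delta 0.001, patience 5); the residual network uses plain SGD at
#' learning rate 0.01 with weight decay 1e-4 and a fixed epoch budget.
#'
#' @param architecture `"alexnet"` or `"resnet12"`.
#' @param n_classes Number of classes.
#' @param epochs Maximum (alexnet) or fixed (resnet12) epoch budget.
#' @param batch_size Minibatch size.
#' @param initial_lr,lr_decay_rate,lr_decay_step Staircase schedule
#'   `initial_lr * lr_decay_rate^((epoch - 1) %/% lr_decay_step)`; set
#'   `lr_decay_rate = 1` for a constant rate.
#' @param momentum_style `"nesterov"` or `"plain-sgd"`.
#' @param momentum Momentum coefficient (ignored for plain SGD).
#' @param weight_decay L2 penalty on convolution/dense weights.
#' @param early_stopping `NULL`, or a list with `min_delta` and `patience`;
#'   monitors test accuracy.
#' @param seed Seed for weight init and batch shuffling.
#' @param dense_units,widths Architecture size knobs (see [build_alexnet()],
#'   [build_resnet12()]).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(architecture = c("alexnet", "resnet12"),
                       n_classes = 8L,
                       epochs = if (architecture == "alexnet") 100L else 15L,
                       batch_size = 32L,
                       initial_lr = 0.01,
                       lr_decay_rate = if (architecture == "alexnet") 0.99 else 1,
                       lr_decay_step = 3L,
                       momentum_style = if (architecture == "alexnet")
                         "nesterov" else "plain-sgd",
                       momentum = 0.9,
                       weight_decay = if (architecture == "alexnet") 0 else 1e-4,
                       early_stopping = if (architecture == "alexnet")
                         list(min_delta = 0.001, patience = 5L) else NULL,
                       seed = 42L,
                       dense_units = 4096L,
                       widths = c(16L, 32L, 64L)) {
  architecture <- match.arg(architecture)
  if (n_classes < 2) stop_parameter("`n_classes` must be >= 2.")
  structure(
    list(architecture = architecture, n_classes = as.integer(n_classes),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         initial_lr = initial_lr, lr_decay_rate = lr_decay_rate,
         lr_decay_step = as.integer(lr_decay_step),
         momentum_style = momentum_style, momentum = momentum,
         weight_decay = weight_decay, early_stopping = early_stopping,
         seed = as.integer(seed), dense_units = as.integer(dense_units),
         widths = as.integer(widths)),
    class = "cnn_config"
  )
}

#' Early-stopping bookkeeping over an accuracy trace
#'
#' Implements the monitor rule: training stops once the monitored accuracy
#' has failed to improve on its best value by more than `min_delta` for
#' `patience` consecutive epochs. Pure function of the trace, used both by
#' [train_cnn()] and directly testable.
#'
#' @param trace Numeric vector of per-epoch monitored accuracies.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param min_delta Minimum improvement that resets the counter.
#' @return List: `stop_epoch` (last epoch run, `NA` if the trace never
#'   triggers), `best_epoch` (earliest epoch attaining the best monitored
#'   value among epochs up to the stop).
#' @export
#' @examples
#' early_stopping_trace(c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
#'                      patience = 5, min_delta = 0.001)
early_stopping_trace <- function(trace, patience = 5L, min_delta = 0.001) {
  best <- -Inf
  best_epoch <- NA_integer_
  wait <- 0L
  for (e in seq_along(trace)) {
    if (trace[e] > best + min_delta) {
      best <- trace[e]
      best_epoch <- e
      wait <- 0L
    } else {
      if (trace[e] > best) {
        # improvement below min_delta: remember it but keep waiting
        best <- trace[e]
        best_epoch <- e
      }
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = best_epoch)
}

#' Train a CNN on labelled image arrays
#'
#' Minimizes softmax cross-entropy by minibatch SGD under the configuration's
#' schedule, evaluating test accuracy each epoch, applying the early-stopping
#' rule when configured, and restoring the best-epoch weights for the final
#' confusion matrix.
#'
#' @param x_train,x_test `H x W x 3 x N` arrays in `[0, 1]`.
#' @param y_train,y_test Integer labels in `0..K-1`.
#' @param config A [cnn_config()].
#' @param verbose Print a per-epoch log line.
#' @return A `cnn_fit`: list with the trained network, per-epoch `curves`
#'   tibble (`epoch`, `lr`, `loss`, `train_accuracy`, `test_accuracy`),
#'   `stopping_epoch`, `best_epoch`, `confusion`, `accuracy`, `sensitivity`,
#'   `elapsed` seconds and the `config`.
#' @export
train_cnn <- function(x_train, y_train, x_test, y_test, config,
                      verbose = FALSE) {
  stopifnot(inherits(config, "cnn_config"))
  if (length(y_train) == 0 || length(y_test) == 0) {
    stop_parameter("Both train and test splits must be non-empty.")
  }
  if (any(c(y_train, y_test) < 0) || any(c(y_train, y_test) >= config$n_classes)) {
    stop_parameter("Labels must lie in 0..K-1.")
  }
  t0 <- proc.time()[["elapsed"]]
  net <- switch(config$architecture,
    alexnet = build_alexnet(config$n_classes, seed = config$seed,
                            dense_units = config$dense_units,
                            input_size = dim(x_train)[1]),
    resnet12 = build_resnet12(config$n_classes, seed = config$seed,
                              widths = config$widths,
                              input_size = dim(x_train)[1])
  )
  n <- dim(x_train)[4]
  nesterov <- config$momentum_style == "nesterov"
  momentum <- if (config$momentum_style == "plain-sgd") 0 else config$momentum

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "shuffle"))

  es <- config$early_stopping
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_snap <- NULL
  wait <- 0L
  curves <- vector("list", config$epochs)
  stopping_epoch <- config$epochs

  for (epoch in seq_len(config$epochs)) {
    lr <- config$initial_lr *
      config$lr_decay_rate^((epoch - 1L) %/% config$lr_decay_step)
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x_train[, , , idx, drop = FALSE]
      yb <- y_train[idx]
      fw <- net_forward(net, xb, training = TRUE)
      lo <- softmax_xent(fw$logits, yb)
      if (!is.finite(lo$loss)) {
        abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch),
              class = "cosid_divergence_error", epoch = epoch)
      }
      ep_loss <- ep_loss + lo$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(t(lo$prob), ties.method = "first") - 1L == yb)
      grads <- net_backward(net, fw$caches, lo$dlogits)
      for (i in seq_along(net$layers)) {
        if (length(grads[[i]])) {
          sgd_step(net$layers[[i]], grads[[i]], lr, momentum, nesterov,
                   config$weight_decay)
        }
      }
    }
    train_acc <- ep_correct / n
    bn_recalibrate(net, x_train, batch_size = config$batch_size)
    test_pred <- predict(net, x_test)
    test_acc <- mean(test_pred$labels == y_test)
    curves[[epoch]] <- tibble(
      epoch = epoch, lr = lr, loss = ep_loss / n,
      train_accuracy = train_acc, test_accuracy = test_acc
    )
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  train %.3f  test %.3f",
                      epoch, lr, ep_loss / n, train_acc, test_acc))
    }
    # track best epoch (earliest attaining the maximum monitored accuracy)
    improved_best <- test_acc > best_acc
    if (is.null(es)) {
      if (improved_best) {
        best_acc <- test_acc
        best_epoch <- epoch
        best_snap <- net_snapshot(net)
      }
    } else {
      if (test_acc > best_acc + es$min_delta) {
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      if (improved_best) {
        best_acc <- test_acc
        best_epoch <- epoch
        best_snap <- net_snapshot(net)
      }
      if (wait >= es$patience) {
        stopping_epoch <- epoch
        break
      }
    }
    stopping_epoch <- epoch
  }

  if (!is.null(best_snap)) net_restore(net, best_snap)
  best_snap <- NULL
  drop_momentum(net$layers)
  final_pred <- predict(net, x_test)
  confusion <- confusion_matrix(y_test, final_pred$labels, config$n_classes)
  curves <- dplyr::bind_rows(curves)
  structure(
    list(
      net = net, curves = curves, stopping_epoch = stopping_epoch,
      best_epoch = best_epoch, confusion = confusion,
      accuracy = accuracy(confusion), sensitivity = sensitivity(confusion),
      train_accuracy = curves$train_accuracy[best_epoch],
      min_loss = min(curves$loss), final_loss = curves$loss[nrow(curves)],
      elapsed = proc.time()[["elapsed"]] - t0, config = config
    ),
    class = "cnn_fit"
  )
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn_fit %s: stopped at epoch %d (best %d), test accuracy %.3f>\n",
    x$config$architecture, x$stopping_epoch, x$best_epoch, x$accuracy
  ))
  invisible(x)
}

#' @rdname predict.cosid_cnn
#' @export
predict.cnn_fit <- function(object, images, ...) {
  predict(object$net, images, ...)
}

#' Tidy per-epoch training curves
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @export
tidy.cnn_fit <- function(x, ...) x$curves

#' One-row training summary
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with stopping/best epoch, losses, accuracies, elapsed time.
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(
    architecture = x$config$architecture,
    stopping_epoch = x$stopping_epoch,
    best_epoch = x$best_epoch,
    min_loss = x$min_loss,
    final_loss = x$final_loss,
    train_accuracy = x$train_accuracy,
    test_accuracy = x$accuracy,
    elapsed = x$elapsed
  )
}

#' Plot accuracy and loss curves of a CNN fit
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object (accuracy and loss per epoch, facetted).
#' @export
autoplot.cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              c("loss", "train_accuracy", "test_accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL)
}
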