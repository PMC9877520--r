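# The two CNN architectures: an Alexnet-style stack and a 12-layer residual
# network, both over 64 x 64 x 3 rasters.

new_cnn <- function(layers, architecture, n_classes, input_size) {
  structure(
    list(layers = layers, architecture = architecture,
         n_classes = as.integer(n_classes), input_size = as.integer(input_size)),
    class = "cosid_cnn"
  )
}

#' Build the Alexnet-style network
#'
#' Layer schedule on a 64x64x3 input: conv 96 @ 11x11 (stride 1, same) +
#' batch norm + 3x3/2 max pool (-> 32); conv 256 @ 5x5 + batch norm + pool
#' (-> 16); conv 384, 384, 256 @ 3x3; pool (-> 8); dense 4096; dense 4096;
#' dense `n_classes` with softmax. Pools use same-padding so the spatial
#' trace is exactly 32/16/8.
#'
#' @param n_classes Number of classes (>= 2).
#' @param seed Seed for the (He) weight initialization.
#' @param dense_units Width of the two fully connected layers (default 4096).
#' @param input_size Input raster side length.
#' @return A `cosid_cnn` model object.
#' @export
build_alexnet <- function(n_classes, seed = 42L, dense_units = 4096L,
                          input_size = 64L) {
  if (n_classes < 2) stop_parameter("`n_classes` must be >= 2.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s8 <- input_size %/% 8L
  layers <- list(
    layer_conv(3, 96, 11L), layer_bn(96), layer_relu(), layer_maxpool(),
    layer_conv(96, 256, 5L), layer_bn(256), layer_relu(), layer_maxpool(),
    layer_conv(256, 384, 3L, bias = TRUE), layer_relu(),
    layer_conv(384, 384, 3L, bias = TRUE), layer_relu(),
    layer_conv(384, 256, 3L, bias = TRUE), layer_relu(), layer_maxpool(),
    layer_flatten(),
    layer_dense(s8 * s8 * 256L, dense_units), layer_relu(),
    layer_dense(dense_units, dense_units), layer_relu(),
    layer_dense(dense_units, n_classes)
  )
  new_cnn(layers, "alexnet", n_classes, input_size)
}

#' Build the 12-layer residual network
#'
#' Stem convolution (3x3, stride 2) + batch norm + ReLU, then an interleaving
#' of two projection (conv) residual blocks - used where the spatial or
#' channel dimension changes - and three identity residual blocks, followed
#' by global average pooling, flatten, and a softmax head. Counting the stem,
#' the ten main-path block convolutions, and the dense head gives 12 weight
#' layers.
#'
#' @inheritParams build_alexnet
#' @param widths Channel widths of the three stages.
#' @return A `cosid_cnn` model object.
#' @export
build_resnet12 <- function(n_classes, seed = 42L, widths = c(16L, 32L, 64L),
                           input_size = 64L) {
  if (n_classes < 2) stop_parameter("`n_classes` must be >= 2.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  w <- as.integer(widths)
  layers <- list(
    layer_conv(3, w[1], 3L, stride = 2L), layer_bn(w[1]), layer_relu(),
    layer_resblock(w[1], w[2], stride = 2L), # conv (projection) block
    layer_resblock(w[2], w[2]),              # identity block
    layer_resblock(w[2], w[3], stride = 2L), # conv (projection) block
    layer_resblock(w[3], w[3]),              # identity block
    layer_resblock(w[3], w[3]),              # identity block
    layer_gap(),
    layer_dense(w[3], n_classes)
  )
  new_cnn(layers, "resnet12", n_classes, input_size)
}

#' @export
print.cosid_cnn <- function(x, ...) {
  cat(sprintf("<cosid_cnn %s: %d classes, input %dx%dx3, %d weight layers>\n",
              x$architecture, x$n_classes, x$input_size, x$input_size,
              count_weight_layers(x)))
  invisible(x)
}

#' Count weight layers (main-path convolutions and dense layers)
#' @param net A `cosid_cnn`.
#' @return Integer count; projection shortcuts and batch norms excluded.
#' @export
count_weight_layers <- function(net) {
  n <- 0L
  for (l in net$layers) {
    if (l$kind %in% c("conv", "dense")) n <- n + 1L
    if (l$kind == "resblock") n <- n + 2L
  }
  n
}

#' Census of residual blocks
#' @param net A `cosid_cnn`.
#' @return Named integer vector `identity` / `projection`.
#' @export
block_census <- function(net) {
  proj <- 0L
  ident <- 0L
  for (l in net$layers) {
    if (l$kind == "resblock") {
      if (l$cfg$project) proj <- proj + 1L else ident <- ident + 1L
    }
  }
  c(identity = ident, projection = proj)
}

#' Spatial shape trace of a network
#'
#' Dry forward pass on a zero image recording the activation shape after
#' every layer; the Alexnet pool trace (32, 16, 8) can be asserted from it.
#'
#' @param net A `cosid_cnn`.
#' @return Tibble with `layer`, `kind`, `shape` (text).
#' @export
net_shape_trace <- function(net) {
  x <- array(0, dim = c(net$input_size, net$input_size, 3, 1))
  rows <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    x <- layer_forward(net$layers[[i]], x, training = FALSE)$y
    d <- if (is.matrix(x)) dim(x) else dim(x)
    rows[[i]] <- tibble(layer = i, kind = net$layers[[i]]$kind,
                        shape = paste(d, collapse = "x"))
  }
  dplyr::bind_rows(rows)
}

#' Class probabilities and labels for a batch of images
#'
#' Deterministic evaluation-mode forward pass (batch-norm uses running
#' statistics).
#'
#' @param object A trained `cosid_cnn` (or `cnn_fit`).
#' @param images `H x W x 3 x N` array scaled to `[0, 1]`.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return List with `labels` (0-based integers) and `prob` (N x K matrix).
#' @export
predict.cosid_cnn <- function(object, images, batch_size = 64L, ...) {
  d <- dim(images)
  if (length(d) != 4 || d[1] != object$input_size || d[2] != object$input_size
      || d[3] != 3) {
    stop_parameter(sprintf(
      "Images must be %dx%dx3xN; got %s.",
      object$input_size, object$input_size, paste(d, collapse = "x")
    ))
  }
  n <- d[4]
  prob <- matrix(NA_real_, n, object$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits <- net_forward(object, images[, , , idx, drop = FALSE],
                          training = FALSE)$logits
    prob[idx, ] <- t(softmax(logits))
  }
  list(labels = max.col(prob, ties.method = "first") - 1L, prob = prob)
}
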