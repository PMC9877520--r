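# Numerical verification of the CNN engine against naive oracles and
# central-difference gradients.

test_that("convolution kernels match a literal nested-loop oracle", {
  set.seed(1)
  x <- array(rnorm(7 * 7 * 2 * 3), c(7, 7, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  for (stride in 1:2) {
    for (same in c(TRUE, FALSE)) {
      got <- cosid:::conv_fwd_cpp(x, dim(x), w, dim(w), stride, same)$y
      want <- naive_conv(x, w, stride, same)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("convolution backward passes a gradient check", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  gy <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  bw <- cosid:::conv_bwd_cpp(x, dim(x), w, dim(w), gy, 1L, TRUE)
  fw_w <- function(wv) {
    sum(cosid:::conv_fwd_cpp(x, dim(x), array(wv, dim(w)), dim(w), 1L, TRUE)$y * gy)
  }
  fw_x <- function(xv) {
    sum(cosid:::conv_fwd_cpp(array(xv, dim(x)), dim(x), w, dim(w), 1L, TRUE)$y * gy)
  }
  iw <- sample(length(w), 6)
  ix <- sample(length(x), 6)
  expect_equal(numeric_grad(fw_w, w, iw), bw$dw[iw], tolerance = 1e-5)
  expect_equal(numeric_grad(fw_x, x, ix), bw$dx[ix], tolerance = 1e-5)
})

test_that("max pooling routes gradients to the argmax positions", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  p <- cosid:::maxpool_fwd_cpp(x, dim(x), 3L, 2L, TRUE)
  expect_equal(dim(p$y), c(3, 3, 2, 2))
  gy <- array(rnorm(length(p$y)), dim(p$y))
  dx <- cosid:::maxpool_bwd_cpp(gy, p$argmax, dim(x))
  expect_equal(sum(dx), sum(gy))
  # per-plane gradient mass is conserved
  expect_equal(apply(dx, 3:4, sum), apply(gy, 3:4, sum))
})

test_that("batch-norm forward/backward pass a gradient check", {
  set.seed(4)
  layer <- cosid:::layer_bn(3)
  layer$params$gamma <- runif(3, 0.5, 1.5)
  layer$params$beta <- rnorm(3)
  x <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))
  gy <- array(rnorm(length(x)), dim(x))
  fw <- cosid:::layer_forward(layer, x, training = TRUE)
  bw <- cosid:::layer_backward(layer, fw$cache, gy)
  f_of_x <- function(xv) {
    sum(cosid:::layer_forward(layer, array(xv, dim(x)), TRUE)$y * gy)
  }
  ix <- sample(length(x), 6)
  expect_equal(numeric_grad(f_of_x, x, ix), bw$dx[ix], tolerance = 1e-4)
  # parameter gradients
  f_of_g <- function(g) {
    l2 <- cosid:::layer_bn(3)
    l2$params$gamma <- g
    l2$params$beta <- layer$params$beta
    sum(cosid:::layer_forward(l2, x, TRUE)$y * gy)
  }
  expect_equal(numeric_grad(f_of_g, layer$params$gamma, 1:3),
               bw$grads$gamma, tolerance = 1e-4)
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(5)
  logits <- matrix(rnorm(4 * 6), 4, 6)
  y <- sample(0:3, 6, replace = TRUE)
  lo <- cosid:::softmax_xent(logits, y)
  f <- function(lv) cosid:::softmax_xent(matrix(lv, 4, 6), y)$loss
  idx <- sample(length(logits), 8)
  expect_equal(numeric_grad(f, logits, idx), lo$dlogits[idx], tolerance = 1e-6)
  expect_equal(colSums(lo$prob), rep(1, 6))
})

test_that("residual blocks keep a live skip connection", {
  set.seed(6)
  block <- cosid:::layer_resblock(4, 4)
  x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  full <- cosid:::layer_forward(block, x, training = FALSE)$y
  # main path alone (shortcut removed): conv1-bn1-relu-conv2-bn2-relu
  s <- block$sub
  h <- cosid:::layer_forward(s$conv1, x, FALSE)$y
  h <- cosid:::layer_forward(s$bn1, h, FALSE)$y
  h <- h * (h > 0)
  h <- cosid:::layer_forward(s$conv2, h, FALSE)$y
  h <- cosid:::layer_forward(s$bn2, h, FALSE)$y
  main_only <- h * (h > 0)
  expect_gt(max(abs(full - main_only)), 1e-6)
  # and the block output equals relu(main + x)
  expect_equal(full, (h + x) * ((h + x) > 0), tolerance = 1e-12)
})
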