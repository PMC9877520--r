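# Minimal CNN engine. Activations are (H, W, C, N) arrays; dense activations
# are (features, N) matrices. Each layer is an environment holding `params`
# (learnable arrays), `state` (batch-norm running statistics) and `mom`
# (momentum buffers), so SGD updates mutate in place without copying the
# whole network. Convolution and pooling call the Rcpp kernels; everything
# else is vectorized R.

new_layer <- function(kind, cfg = list(), params = list(), state = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$cfg <- cfg
  e$params <- params
  e$state <- state
  e$mom <- lapply(params, function(p) p * 0)
  class(e) <- "cosid_layer"
  e
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

layer_conv <- function(in_c, out_c, k, stride = 1L, same = TRUE, bias = FALSE) {
  params <- list(W = he_init(c(k, k, in_c, out_c), k * k * in_c))
  if (bias) params$b <- numeric(out_c)
  new_layer("conv", list(stride = as.integer(stride), same = same), params)
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", list(momentum = momentum, eps = eps),
            params = list(gamma = rep(1, c), beta = rep(0, c)),
            state = list(run_mean = rep(0, c), run_var = rep(1, c)))
}

layer_relu <- function() new_layer("relu")

layer_maxpool <- function(k = 3L, stride = 2L, same = TRUE) {
  new_layer("maxpool", list(k = as.integer(k), stride = as.integer(stride),
                            same = same))
}

layer_flatten <- function() new_layer("flatten")

layer_gap <- function() new_layer("gap")

layer_dense <- function(in_dim, out_dim) {
  new_layer("dense", list(),
            list(W = matrix(rnorm(out_dim * in_dim, 0, sqrt(2 / in_dim)),
                            out_dim, in_dim),
                 b = numeric(out_dim)))
}

layer_resblock <- function(in_c, out_c, stride = 1L) {
  project <- (in_c != out_c) || (stride != 1L)
  sub <- list(
    conv1 = layer_conv(in_c, out_c, 3L, stride = stride),
    bn1 = layer_bn(out_c),
    conv2 = layer_conv(out_c, out_c, 3L),
    bn2 = layer_bn(out_c)
  )
  if (project) {
    sub$proj_conv <- layer_conv(in_c, out_c, 1L, stride = stride)
    sub$proj_bn <- layer_bn(out_c)
  }
  e <- new_layer("resblock", list(project = project))
  e$sub <- sub
  e
}

# per-channel reductions over (HW, C, N) flattening
channel_sum <- function(a, HW, C, N) {
  rowSums(matrix(colSums(matrix(a, HW, C * N)), C, N))
}

expand_ch <- function(v, HW) rep(v, each = HW)

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  HW <- d[1] * d[2]
  C <- d[3]
  N <- d[4]
  eps <- layer$cfg$eps
  if (training) {
    M <- HW * N
    mu <- channel_sum(x, HW, C, N) / M
    xc <- x - expand_ch(mu, HW)
    var <- channel_sum(xc * xc, HW, C, N) / M
    mom <- layer$cfg$momentum
    layer$state$run_mean <- mom * layer$state$run_mean + (1 - mom) * mu
    layer$state$run_var <- mom * layer$state$run_var + (1 - mom) * var
    if (isTRUE(layer$state$calibrating)) {
      layer$state$acc_sum <- layer$state$acc_sum + mu * M
      layer$state$acc_sumsq <- layer$state$acc_sumsq + (var + mu^2) * M
      layer$state$acc_n <- layer$state$acc_n + M
    }
  } else {
    mu <- layer$state$run_mean
    var <- layer$state$run_var
    xc <- x - expand_ch(mu, HW)
  }
  inv_sd <- 1 / sqrt(var + eps)
  xhat <- xc * expand_ch(inv_sd, HW)
  y <- xhat * expand_ch(layer$params$gamma, HW) +
    expand_ch(layer$params$beta, HW)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, HW = HW, C = C,
                           N = N, training = training))
}

bn_backward <- function(layer, cache, dy) {
  HW <- cache$HW
  C <- cache$C
  N <- cache$N
  M <- HW * N
  xhat <- cache$xhat
  dgamma <- channel_sum(dy * xhat, HW, C, N)
  dbeta <- channel_sum(dy, HW, C, N)
  dxhat <- dy * expand_ch(layer$params$gamma, HW)
  if (cache$training) {
    # dx = inv_sd/M * (M*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- channel_sum(dxhat, HW, C, N)
    s2 <- channel_sum(dxhat * xhat, HW, C, N)
    dx <- expand_ch(cache$inv_sd / M, HW) *
      (M * dxhat - expand_ch(s1, HW) - xhat * expand_ch(s2, HW))
  } else {
    dx <- dxhat * expand_ch(cache$inv_sd, HW)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layer_forward <- function(layer, x, training) {
  switch(layer$kind,
    conv = {
      r <- conv_fwd_cpp(x, dim(x), layer$params$W, dim(layer$params$W),
                        layer$cfg$stride, layer$cfg$same)
      y <- r$y
      if (!is.null(layer$params$b)) {
        d <- dim(y)
        y <- y + expand_ch(rep(layer$params$b, d[4]), d[1] * d[2])
      }
      list(y = y, cache = list(x = x))
    },
    bn = bn_forward(layer, x, training),
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    maxpool = {
      r <- maxpool_fwd_cpp(x, dim(x), layer$cfg$k, layer$cfg$stride,
                           layer$cfg$same)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, prod(d[1:3]), d[4]), cache = list(xdim = d))
    },
    gap = {
      d <- dim(x)
      HW <- d[1] * d[2]
      y <- matrix(colSums(matrix(x, HW, d[3] * d[4])) / HW, d[3], d[4])
      list(y = y, cache = list(xdim = d))
    },
    dense = {
      list(y = layer$params$W %*% x + layer$params$b, cache = list(x = x))
    },
    resblock = resblock_forward(layer, x, training),
    abort(paste("Unknown layer kind:", layer$kind))
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    conv = {
      r <- conv_bwd_cpp(cache$x, dim(cache$x), layer$params$W,
                        dim(layer$params$W), dy, layer$cfg$stride,
                        layer$cfg$same)
      grads <- list(W = r$dw)
      if (!is.null(layer$params$b)) {
        d <- dim(dy)
        grads$b <- channel_sum(dy, d[1] * d[2], d[3], d[4])
      }
      list(dx = r$dx, grads = grads)
    },
    bn = bn_backward(layer, cache, dy),
    relu = list(dx = dy * cache$mask, grads = list()),
    maxpool = list(dx = maxpool_bwd_cpp(dy, cache$argmax, cache$xdim),
                   grads = list()),
    flatten = list(dx = array(dy, dim = cache$xdim), grads = list()),
    gap = {
      d <- cache$xdim
      HW <- d[1] * d[2]
      dx <- array(expand_ch(as.vector(dy), HW) / HW, dim = d)
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = crossprod(layer$params$W, dy),
           grads = list(W = tcrossprod(dy, cache$x), b = rowSums(dy)))
    },
    resblock = resblock_backward(layer, cache, dy),
    abort(paste("Unknown layer kind:", layer$kind))
  )
}

resblock_forward <- function(layer, x, training) {
  s <- layer$sub
  f1 <- layer_forward(s$conv1, x, training)
  f2 <- layer_forward(s$bn1, f1$y, training)
  a1 <- f2$y * (f2$y > 0)
  mask1 <- f2$y > 0
  f3 <- layer_forward(s$conv2, a1, training)
  f4 <- layer_forward(s$bn2, f3$y, training)
  if (layer$cfg$project) {
    p1 <- layer_forward(s$proj_conv, x, training)
    p2 <- layer_forward(s$proj_bn, p1$y, training)
    short <- p2$y
    pcache <- list(p1 = p1$cache, p2 = p2$cache)
  } else {
    short <- x
    pcache <- NULL
  }
  pre <- f4$y + short
  mask2 <- pre > 0
  list(y = pre * mask2,
       cache = list(c1 = f1$cache, b1 = f2$cache, mask1 = mask1,
                    c2 = f3$cache, b2 = f4$cache, p = pcache,
                    mask2 = mask2))
}

resblock_backward <- function(layer, cache, dy) {
  s <- layer$sub
  dpre <- dy * cache$mask2
  b2 <- layer_backward(s$bn2, cache$b2, dpre)
  c2 <- layer_backward(s$conv2, cache$c2, b2$dx)
  da1 <- c2$dx * cache$mask1
  b1 <- layer_backward(s$bn1, cache$b1, da1)
  c1 <- layer_backward(s$conv1, cache$c1, b1$dx)
  grads <- list(conv1 = c1$grads, bn1 = b1$grads, conv2 = c2$grads,
                bn2 = b2$grads)
  if (layer$cfg$project) {
    p2 <- layer_backward(s$proj_bn, cache$p$p2, dpre)
    p1 <- layer_backward(s$proj_conv, cache$p$p1, p2$dx)
    dx <- c1$dx + p1$dx
    grads$proj_conv <- p1$grads
    grads$proj_bn <- p2$grads
  } else {
    dx <- c1$dx + dpre
  }
  list(dx = dx, grads = grads)
}

# forward/backward over the whole stack ---------------------------------------

net_forward <- function(net, x, training = FALSE, keep_cache = training) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training)
    x <- r$y
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(logits = x, caches = caches)
}

net_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  dy <- dlogits
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  grads
}

softmax <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# labels are 0-based; returns loss and dlogits
softmax_xent <- function(logits, labels) {
  p <- softmax(logits)
  n <- ncol(p)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}

# SGD with optional Nesterov momentum and decoupled-from-BN weight decay
# (decay applies to conv/dense weight matrices only).
sgd_step <- function(layer, grads, lr, momentum, nesterov, weight_decay) {
  if (layer$kind == "resblock") {
    for (nm in names(grads)) {
      sgd_step(layer$sub[[nm]], grads[[nm]], lr, momentum, nesterov,
               weight_decay)
    }
    return(invisible())
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm == "W" && weight_decay > 0) g <- g + weight_decay * layer$params[[nm]]
    if (momentum > 0) {
      v <- momentum * layer$mom[[nm]] + g
      layer$mom[[nm]] <- v
      step <- if (nesterov) g + momentum * v else v
    } else {
      step <- g
    }
    layer$params[[nm]] <- layer$params[[nm]] - lr * step
  }
  invisible()
}

# Precise batch-norm recalibration: after the epoch's weight updates, the
# exponential running averages lag the (fast-moving) activation statistics,
# which wrecks evaluation-mode accuracy when an epoch holds only a handful of
# minibatches. A single training-mode pass over the training set accumulates
# exact per-channel moments, which then replace the running statistics.
walk_bn <- function(layers, fn) {
  for (l in layers) {
    if (l$kind == "bn") fn(l)
    if (l$kind == "resblock") walk_bn(l$sub, fn)
  }
  invisible()
}

bn_recalibrate <- function(net, x, batch_size = 64L) {
  walk_bn(net$layers, function(l) {
    C <- length(l$params$gamma)
    l$state$calibrating <- TRUE
    l$state$acc_sum <- numeric(C)
    l$state$acc_sumsq <- numeric(C)
    l$state$acc_n <- 0
  })
  n <- dim(x)[4]
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    net_forward(net, x[, , , idx, drop = FALSE], training = TRUE,
                keep_cache = FALSE)
  }
  walk_bn(net$layers, function(l) {
    mu <- l$state$acc_sum / l$state$acc_n
    l$state$run_mean <- mu
    l$state$run_var <- pmax(l$state$acc_sumsq / l$state$acc_n - mu^2, 0)
    l$state$calibrating <- FALSE
    l$state$acc_sum <- l$state$acc_sumsq <- l$state$acc_n <- NULL
  })
  invisible(net)
}

# momentum buffers are training-only state; freeing them halves a trained
# model's footprint
drop_momentum <- function(layers) {
  for (l in layers) {
    l$mom <- lapply(l$params, function(p) NULL)
    if (l$kind == "resblock") drop_momentum(l$sub)
  }
  invisible()
}

# deep copy of learnable/running state (for best-epoch snapshots)
net_snapshot <- function(net) {
  lapply(net$layers, layer_snapshot)
}

layer_snapshot <- function(layer) {
  s <- list(params = layer$params, state = layer$state)
  if (layer$kind == "resblock") s$sub <- lapply(layer$sub, layer_snapshot)
  s
}

net_restore <- function(net, snap) {
  for (i in seq_along(net$layers)) layer_restore(net$layers[[i]], snap[[i]])
  invisible(net)
}

layer_restore <- function(layer, s) {
  layer$params <- s$params
  layer$state <- s$state
  if (layer$kind == "resblock") {
    for (nm in names(s$sub)) layer_restore(layer$sub[[nm]], s$sub[[nm]])
  }
  invisible()
}
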