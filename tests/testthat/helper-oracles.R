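# Independent oracles used across the suite. Each re-derives the quantity by
# the most literal route available (explicit loops, closed forms) and never
# calls the implementation path it checks.

# Literal double-loop evaluation of the synchronous and asynchronous maps
# from an m x n perturbation matrix.
brute_force_cos <- function(P) {
  m <- nrow(P)
  n <- ncol(P)
  N <- matrix(0, m, m)
  for (j in 1:m) for (k in 1:m) if (j != k) N[j, k] <- 1 / (pi * (k - j))
  sync <- matrix(0, n, n)
  asyn <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      sync[i, j] <- sum(P[, i] * P[, j]) / (m - 1)
      acc <- 0
      for (t in 1:m) for (u in 1:m) acc <- acc + P[t, i] * N[t, u] * P[u, j]
      asyn[i, j] <- acc / (m - 1)
    }
  }
  list(sync = sync, asyn = asyn, integ = sync * asyn)
}

# Literal greedy Kennard-Stone trace with explicit loops.
naive_kennard_stone <- function(features, n_train) {
  features <- as.matrix(features)
  N <- nrow(features)
  d2 <- function(i, j) sqrt(sum((features[i, ] - features[j, ])^2))
  best <- c(NA, NA)
  best_d <- -Inf
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      if (d2(i, j) > best_d) {
        best_d <- d2(i, j)
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_train) {
    cand_best <- NA
    cand_d <- -Inf
    for (i in setdiff(1:N, sel)) {
      mind <- min(vapply(sel, function(s) d2(i, s), numeric(1)))
      if (mind > cand_d) {
        cand_d <- mind
        cand_best <- i
      }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# Direct (nested-loop) spatial convolution for tiny tensors.
naive_conv <- function(x, w, stride, same) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]; F <- dim(w)[4]
  if (same) {
    Ho <- ceiling(H / stride); ph <- max((Ho - 1) * stride + k - H, 0) %/% 2
    Wo <- ceiling(W / stride); pw <- max((Wo - 1) * stride + k - W, 0) %/% 2
  } else {
    Ho <- (H - k) %/% stride + 1; Wo <- (W - k) %/% stride + 1; ph <- pw <- 0
  }
  y <- array(0, c(Ho, Wo, F, N))
  for (n in 1:N) for (f in 1:F) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- 0
    for (c in 1:C) for (dw in 1:k) for (dh in 1:k) {
      hi <- (ho - 1) * stride - ph + dh
      wi <- (wo - 1) * stride - pw + dw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[hi, wi, c, n] * w[dh, dw, c, f]
      }
    }
    y[ho, wo, f, n] <- acc
  }
  y
}

# A small deterministic collection for plumbing tests.
tiny_collection <- function(n_classes = 2, n_per_class = 3, replicates = 2,
                            noise_sd = 0.01, seed = 7) {
  simulate_collection(
    make_default_profiles(n_classes, seed = seed),
    n_per_class, replicates, noise_sd, seed = seed
  )
}

# central-difference gradient of a scalar function at selected indices
numeric_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
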