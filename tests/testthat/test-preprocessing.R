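make_manual_collection <- function(spectra, labels, wavenumber,
                                   replicates = NULL) {
  n <- length(spectra)
  if (is.null(replicates)) replicates <- rep(1L, n)
  new_mir_collection(
    tibble::tibble(
      sample_id = paste0("s", rep(seq_len(n %/% max(replicates)),
                                  each = max(replicates)))[seq_len(n)],
      replicate = replicates,
      label = as.integer(labels),
      class_name = paste0("class_", labels),
      absorbance = spectra
    ),
    wavenumber
  )
}

test_that("replicate averaging is the arithmetic mean and preserves labels", {
  w <- c(30, 20, 10)
  coll <- make_manual_collection(
    list(c(0, 2, 4), c(2, 0, 0)), labels = c(0, 0), wavenumber = w,
    replicates = c(1L, 2L)
  )
  avg <- average_replicates(coll)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$absorbance[[1]], c(1, 1, 2))
  expect_equal(avg$label, 0L)

  single <- make_manual_collection(list(c(1, 2, 3)), 1, w)
  expect_equal(average_replicates(single)$absorbance[[1]], c(1, 2, 3))
})

test_that("averaging a replicated collection halves the spectrum count", {
  coll <- tiny_collection(8, 10, 2)
  expect_equal(nrow(average_replicates(coll)), 80)
})

test_that("replicate averaging is invariant to replicate order", {
  coll <- tiny_collection(2, 3, 3)
  shuffled <- coll[rev(seq_len(nrow(coll))), ]
  a1 <- average_replicates(coll)
  a2 <- average_replicates(shuffled)
  a2 <- a2[match(a1$sample_id, a2$sample_id), ]
  expect_equal(a1$absorbance, a2$absorbance)
})

test_that("fingerprint truncation keeps the closed interval and is idempotent", {
  coll <- tiny_collection(2, 1, 1)
  tr <- truncate_fingerprint(coll)
  w <- wavenumbers(tr)
  expect_equal(length(w), 338)
  expect_equal(max(w), 1748)
  expect_equal(min(w), 400)
  expect_equal(wavenumbers(truncate_fingerprint(tr)), w)
  # full-range interval is the identity
  expect_equal(wavenumbers(truncate_fingerprint(coll, 4000, 400)),
               wavenumbers(coll))
  expect_error(truncate_fingerprint(coll, 200, 100),
               class = "cosid_parameter_error")
})

test_that("class means are pointwise means bounded by per-class extremes", {
  w <- c(30, 20, 10)
  coll <- make_manual_collection(list(c(1, 3, 5), c(3, 1, 1)), c(0, 0), w)
  coll$sample_id <- c("a", "b")
  cm <- compute_class_mean(coll, 0)
  expect_equal(cm$absorbance[[1]], c(2, 2, 3))
  expect_equal(cm$label, 0L)

  one <- make_manual_collection(list(c(9, 9, 9)), 1, w)
  expect_equal(compute_class_mean(one, 1)$absorbance[[1]], c(9, 9, 9))
  expect_error(compute_class_mean(one, 0), class = "cosid_parameter_error")

  # noise-free class: mean equals the shared spectrum exactly
  nf <- simulate_collection(make_default_profiles(2, seed = 1), 5, 1, 0, 1)
  cm0 <- compute_class_mean(nf, 0)
  expect_equal(cm0$absorbance[[1]], nf$absorbance[[which(nf$label == 0)[1]]],
               tolerance = 1e-15)

  # bounded by min/max pointwise
  noisy <- tiny_collection(2, 6, 1)
  m <- spectra_matrix(noisy[noisy$label == 0, ])
  cm <- compute_class_mean(noisy, 0)$absorbance[[1]]
  expect_true(all(cm >= apply(m, 2, min) - 1e-12))
  expect_true(all(cm <= apply(m, 2, max) + 1e-12))
})
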