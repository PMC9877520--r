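test_that("the Hilbert-Noda matrix matches its closed form exactly", {
  expect_identical(hilbert_noda(1), matrix(0, 1, 1))
  expect_equal(hilbert_noda(2),
               matrix(c(0, -1 / pi, 1 / pi, 0), 2, 2))
  expect_equal(hilbert_noda(3),
               matrix(c(0, -1 / pi, -1 / (2 * pi),
                        1 / pi, 0, -1 / pi,
                        1 / (2 * pi), 1 / pi, 0), 3, 3))
  for (m in 1:10) {
    N <- hilbert_noda(m)
    for (j in seq_len(m)) {
      for (k in seq_len(m)) {
        expect_identical(N[j, k], if (j == k) 0 else 1 / (pi * (k - j)))
      }
    }
    expect_equal(N, -t(N))
  }
  expect_error(hilbert_noda(0), class = "cosid_parameter_error")
})

test_that("the perturbation matrix stacks mean then sample", {
  P <- build_perturbation_matrix(c(1, 2), c(3, 4))
  expect_equal(P$P, rbind(c(1, 2), c(3, 4)))
  Pe <- build_perturbation_matrix(c(5, 6), c(5, 6))
  expect_equal(Pe$P[1, ], Pe$P[2, ])
  w <- seq(1748, 400, by = -4)
  Pn <- build_perturbation_matrix(rnorm(338), rnorm(338), wavenumber = w)
  expect_equal(dim(Pn$P), c(2, 338))
  expect_error(
    build_perturbation_matrix(
      new_mir_collection(tibble::tibble(
        sample_id = "a", replicate = 1L, label = 0L, class_name = "c",
        absorbance = list(c(1, 2))), c(20, 10)),
      new_mir_collection(tibble::tibble(
        sample_id = "b", replicate = 1L, label = 0L, class_name = "c",
        absorbance = list(c(1, 2))), c(30, 20))
    ),
    class = "cosid_grid_error"
  )
})

test_that("worked two-point example reproduces the hand-computed maps", {
  P <- rbind(c(1, 2), c(3, 4))
  s <- synchronous_map(P)
  expect_equal(s$values, rbind(c(10, 14), c(14, 20)))
  a <- asynchronous_map(P)
  expect_equal(a$values[1, 2], -2 / pi)
  expect_equal(diag(a$values), c(0, 0))
  i <- integrative_map(s, a)
  expect_equal(i$values[1, 2], -28 / pi)
})

test_that("closed forms hold for degenerate perturbation rows", {
  s <- c(1.5, -2, 0.5, 3)
  dup <- synchronous_map(rbind(s, s))
  expect_equal(dup$values, 2 * outer(s, s))
  # proportional rows annihilate the asynchronous map
  a <- asynchronous_map(rbind(s, 2.5 * s))
  expect_equal(max(abs(a$values)), 0)
  # zero asynchronous map absorbs the integrative product
  i <- integrative_map(synchronous_map(rbind(s, 2.5 * s)), a)
  expect_equal(max(abs(i$values)), 0)
})

test_that("maps agree with brute-force evaluation for random P", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:4, 1)
    n <- sample(2:6, 1)
    P <- matrix(rnorm(m * n), m, n)
    oracle <- brute_force_cos(P)
    s <- synchronous_map(P)$values
    a <- asynchronous_map(P)$values
    expect_lt(max(abs(s - oracle$sync)), 1e-12)
    expect_lt(max(abs(a - oracle$asyn)), 1e-12)
    expect_lt(max(abs(integrative_map(synchronous_map(P),
                                      asynchronous_map(P))$values -
                      oracle$integ)), 1e-12)
    # structural invariants
    expect_identical(s, t(s))
    expect_equal(a, -t(a))
    expect_identical(diag(a), rep(0, n))
  }
})

test_that("asynchronous maps scale linearly in the sample spectrum", {
  set.seed(7)
  m <- rnorm(5)
  s <- rnorm(5)
  base <- asynchronous_map(rbind(m, s))$values
  for (c in c(0.5, 2, -3)) {
    scaled <- asynchronous_map(rbind(m, c * s))$values
    expect_equal(scaled, c * base)
  }
})

test_that("kind and shape mismatches are rejected", {
  P <- rbind(c(1, 2), c(3, 4))
  s <- synchronous_map(P)
  a <- asynchronous_map(P)
  expect_error(integrative_map(a, s), class = "cosid_parameter_error")
  expect_error(synchronous_map(matrix(1:3, 1)), class = "cosid_parameter_error")
  expect_error(asynchronous_map(matrix(1:3, 1)), class = "cosid_parameter_error")
})

test_that("transform_collection emits three deterministic maps per sample", {
  coll <- truncate_fingerprint(average_replicates(tiny_collection(2, 5, 1)))
  maps <- transform_collection(coll)
  expect_length(maps, 10)
  expect_true(all(vapply(maps, length, integer(1)) == 3))
  expect_equal(dim(maps[[1]]$sync$values), c(338, 338))
  maps2 <- transform_collection(coll)
  expect_identical(maps, maps2)
  # reference lacking one class
  ref <- class_mean_spectra(coll)["0"]
  expect_error(transform_collection(coll, ref),
               class = "cosid_parameter_error")
})
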