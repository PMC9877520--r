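test_that("default profiles share the common band set and are reproducible", {
  profs <- make_default_profiles(8, seed = 7)
  expect_equal(nrow(profs), 8)
  # every class carries the chitin band at 1,080 cm^-1
  expect_true(all(vapply(profs$bands, function(b) 1080 %in% b$center,
                         logical(1))))
  expect_identical(make_default_profiles(2, seed = 0),
                   make_default_profiles(2, seed = 0))
  a <- make_default_profiles(2, seed = 0)
  b <- make_default_profiles(2, seed = 1)
  expect_false(isTRUE(all.equal(a$bands[[1]]$height, b$bands[[1]]$height)))
})

test_that("any two profiles differ by >= 10% in at least one band height", {
  profs <- make_default_profiles(8, seed = 3)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      h1 <- profs$bands[[i]]$height
      h2 <- profs$bands[[j]]$height
      expect_gte(max(pmax(h1, h2) / pmin(h1, h2)), 1.1)
    }
  }
})

test_that("profile count is validated", {
  expect_error(make_default_profiles(1), class = "cosid_parameter_error")
  expect_error(make_default_profiles(65), class = "cosid_parameter_error")
})

test_that("a noise-free single-band spectrum peaks at its center height", {
  prof <- list(class_id = 0L, class_name = "x", baseline_slope = 0,
               bands = tibble::tibble(center = 1000, width = 10, height = 1))
  sp <- simulate_spectrum(prof, noise_sd = 0, seed = 1)
  w <- wavenumbers(sp)
  at_center <- sp$absorbance[[1]][which.min(abs(w - 1000))]
  expect_equal(at_center, 1.0, tolerance = 1e-6)
})

test_that("noise-free simulation ignores the seed; noisy simulation replays it", {
  prof <- make_default_profiles(2, seed = 1)[1, ]
  s1 <- simulate_spectrum(prof, noise_sd = 0, seed = 1)
  s2 <- simulate_spectrum(prof, noise_sd = 0, seed = 999)
  expect_identical(s1$absorbance, s2$absorbance)
  n1 <- simulate_spectrum(prof, noise_sd = 0.01, seed = 3)
  n2 <- simulate_spectrum(prof, noise_sd = 0.01, seed = 3)
  expect_identical(n1$absorbance, n2$absorbance)
  n3 <- simulate_spectrum(prof, noise_sd = 0.01, seed = 4)
  expect_false(identical(n1$absorbance, n3$absorbance))
})

test_that("collection counts and labels follow the design", {
  coll <- tiny_collection(8, 10, 2)
  expect_equal(nrow(coll), 160)
  two <- simulate_collection(make_default_profiles(2, seed = 0), 1, 1, 0, 0)
  expect_equal(nrow(two), 2)
  expect_setequal(two$label, c(0L, 1L))
})

test_that("collections round-trip through CSV within 1e-9 and byte-identically", {
  coll <- tiny_collection(4, 5, 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_collection(coll, d1)
  write_collection(coll, d2)
  expect_identical(readBin(file.path(d1, "spectra.csv"), "raw", 1e7),
                   readBin(file.path(d2, "spectra.csv"), "raw", 1e7))
  back <- read_collection(d1)
  expect_equal(wavenumbers(back), wavenumbers(coll))
  expect_identical(back$label[order(back$sample_id, back$replicate)],
                   coll$label[order(coll$sample_id, coll$replicate)])
  m1 <- spectra_matrix(coll)
  m2 <- spectra_matrix(back)[rownames(spectra_matrix(coll)), ]
  expect_lt(max(abs(m1 - m2)), 1e-9)
})

test_that("malformed CSVs raise format errors naming the problem", {
  coll <- tiny_collection(2, 2, 1)
  d <- withr::local_tempdir()
  write_collection(coll, d)
  # blank out one absorbance cell
  lines <- readLines(file.path(d, "spectra.csv"))
  parts <- strsplit(lines[5], ",")[[1]]
  parts[2] <- ""
  lines[5] <- paste(parts, collapse = ",")
  writeLines(lines, file.path(d, "spectra.csv"))
  expect_error(read_collection(d), "line", class = "cosid_format_error")

  # manifest with a non-contiguous label set
  d2 <- withr::local_tempdir()
  write_collection(coll, d2)
  mf <- readr::read_csv(file.path(d2, "manifest.csv"), show_col_types = FALSE)
  mf$label[mf$label == 1] <- 5
  readr::write_csv(mf, file.path(d2, "manifest.csv"))
  expect_error(read_collection(d2), class = "cosid_format_error")

  # spectra column not in the manifest
  d3 <- withr::local_tempdir()
  write_collection(coll, d3)
  sp <- readLines(file.path(d3, "spectra.csv"))
  sp[1] <- sub("species_01_s001__r1", "mystery__r1", sp[1])
  writeLines(sp, file.path(d3, "spectra.csv"))
  expect_error(read_collection(d3), "mystery", class = "cosid_format_error")
})

test_that("class means of noisy spectra converge to the noise-free spectrum", {
  prof <- make_default_profiles(2, seed = 5)[1, ]
  clean <- simulate_spectrum(prof, noise_sd = 0, seed = 1)$absorbance[[1]]
  mad_at <- function(n, seed0) {
    acc <- 0
    for (s in seq_len(n)) {
      acc <- acc + simulate_spectrum(prof, noise_sd = 0.05,
                                     seed = seed0 + s)$absorbance[[1]]
    }
    mean(abs(acc / n - clean))
  }
  m10 <- mad_at(10, 100)
  m1000 <- mad_at(1000, 5000)
  # 1/sqrt(n) shrinkage: factor ~10 expected between n=10 and n=1000
  expect_lt(m1000, m10 / 3)
})

test_that("noise-free spectra of the same class are identical", {
  coll <- simulate_collection(make_default_profiles(3, seed = 2), 4, 1, 0, 9)
  for (k in 0:2) {
    specs <- coll$absorbance[coll$label == k]
    for (i in 2:length(specs)) expect_identical(specs[[i]], specs[[1]])
  }
})
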