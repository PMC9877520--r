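zero_map <- function(n = 12, kind = "synchronous") {
  cosid:::new_cos_map(matrix(0, n, n), kind, NULL, "z")
}

random_map <- function(n = 21, kind = "synchronous", seed = 1) {
  set.seed(seed)
  V <- matrix(rnorm(n * n), n, n)
  if (kind == "synchronous") V <- V + t(V)
  cosid:::new_cos_map(V, kind, NULL, "r")
}

test_that("1D rendering draws a deterministic axis-free curve", {
  flat <- render_1d(rep(1, 100))
  expect_equal(dim(flat$pixels), c(64, 64, 3))
  # constant spectrum: exactly one black row, identical across channels
  dark_rows <- which(apply(flat$pixels[, , 1], 1, function(r) any(r == 0)))
  expect_length(dark_rows, 1)
  spec <- sin(seq(0, 6, length.out = 338))
  expect_identical(render_1d(spec)$pixels, render_1d(spec)$pixels)
  expect_error(render_1d(spec, size = 4), class = "cosid_parameter_error")
})

test_that("2D heatmaps use symmetric colour limits about zero", {
  z <- render_2d(zero_map())
  # uniform midpoint colour
  expect_equal(length(unique(as.vector(z$pixels[, , 1]))), 1)
  expect_equal(dim(z$pixels), c(64, 64, 3))
  expect_equal(z$kind, "sync2D")

  m <- random_map(21)
  img <- render_2d(m)
  neg <- render_2d(cosid:::new_cos_map(-m$values, m$kind, NULL, "r"))
  # negating the map mirrors the colormap pixelwise
  pal <- cosid:::cos_palette()
  for (px in list(c(3, 7), c(20, 41), c(64, 1))) {
    rgb1 <- img$pixels[px[1], px[2], ]
    i1 <- which(pal[, 1] == rgb1[1] & pal[, 2] == rgb1[2] & pal[, 3] == rgb1[3])
    rgb2 <- neg$pixels[px[1], px[2], ]
    i2 <- which(pal[, 1] == rgb2[1] & pal[, 2] == rgb2[2] & pal[, 3] == rgb2[3])
    expect_true(any(outer(i1, i2, function(a, b) a + b == 257)))
  }
  big <- render_2d(cosid:::new_cos_map(matrix(rnorm(338^2), 338), "integrative",
                                       NULL, "big"))
  expect_equal(dim(big$pixels), c(64, 64, 3))
  expect_equal(big$kind, "int2D")
})

test_that("synchronous heatmaps are transpose-symmetric up to resampling", {
  m <- random_map(35, seed = 4)
  img <- render_2d(m)$pixels
  flipped <- aperm(img, c(2, 1, 3))
  expect_lt(mean(abs(img - flipped)) / 255, 2 / 255)
})

test_that("3D surface rendering is deterministic and flat for zero maps", {
  z1 <- render_3d(zero_map(12))
  z2 <- render_3d(zero_map(25))
  expect_identical(z1$pixels, z2$pixels)
  expect_equal(dim(z1$pixels), c(64, 64, 3))
  m <- random_map(30, "asynchronous", seed = 2)
  expect_identical(render_3d(m)$pixels, render_3d(m)$pixels)
  expect_equal(render_3d(m)$kind, "async3D")
  # the flat zero surface must show only the midpoint colour and background
  cols <- unique(matrix(z1$pixels, ncol = 3), MARGIN = 1)
  expect_lte(nrow(cols), 2)
})

test_that("batch generation writes 7 PNGs per sample under kind/class trees", {
  coll <- truncate_fingerprint(average_replicates(tiny_collection(3, 1, 1)))
  out <- withr::local_tempdir()
  man <- batch_generate(coll, out)
  expect_equal(nrow(man), 21)
  on_disk <- list.files(out, recursive = TRUE, pattern = "\\.png$")
  expect_equal(length(on_disk), 21)
  expect_true(all(file.exists(man$path)))
  expect_setequal(unique(man$dimension_kind), cosid:::IMAGE_KINDS)
  # paths follow out/<kind>/<class>/<sample>.png
  expect_true(all(grepl("sync2D|async2D|int2D|sync3D|async3D|int3D|1D",
                        dirname(man$path))))
  # unwritable target: a plain file in place of the directory
  blocker <- withr::local_tempfile(lines = "x")
  expect_error(batch_generate(coll, blocker), class = "cosid_io_error")
})

test_that("rendered arrays align with the collection order and labels", {
  coll <- truncate_fingerprint(average_replicates(tiny_collection(2, 2, 1)))
  arrs <- render_image_arrays(coll, kinds = c("1D", "sync2D"))
  expect_equal(dim(arrs$sync2D), c(64, 64, 3, 4))
  expect_identical(attr(arrs$sync2D, "label"), coll$label)
  expect_true(all(arrs$sync2D >= 0 & arrs$sync2D <= 1))
})
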