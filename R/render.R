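# Rasterization of the seven dataset kinds. Rendering bypasses any plotting
# engine: maps are resampled bilinearly, passed through a fixed diverging
# colormap with limits symmetric about zero, and (for the 3D kinds) projected
# as a surface from a frozen viewpoint. Every renderer is a pure function of
# its inputs, so re-runs are byte-identical.

IMAGE_KINDS <- c("1D", "sync2D", "async2D", "int2D", "sync3D", "async3D", "int3D")

# 256-entry diverging blue-white-red palette, symmetric about its midpoint.
cos_palette <- local({
  pal <- NULL
  function() {
    if (is.null(pal)) {
      cols <- grDevices::colorRampPalette(
        c("#313695", "#FFFFFF", "#A50026"), space = "rgb"
      )(256)
      pal <<- t(grDevices::col2rgb(cols)) # 256 x 3 integer
    }
    pal
  }
})

# Map values already normalized to [-1, 1] onto palette indices 1..256 such
# that idx(u) + idx(-u) = 257 away from exact bin edges (mirror property).
palette_index <- function(u) {
  pmin(256L, 1L + as.integer(floor((u + 1) / 2 * 256)))
}

# Interpolation matrix W (size x n): out = W %*% values resamples a length-n
# axis to `size` points bilinearly, sampling at cell centers.
bilinear_matrix <- function(n, size) {
  W <- matrix(0, size, n)
  src <- (seq_len(size) - 0.5) * n / size + 0.5
  src <- pmin(pmax(src, 1), n)
  j0 <- pmin(floor(src), n - 1)
  wgt <- src - j0
  for (i in seq_len(size)) {
    W[i, j0[i]] <- W[i, j0[i]] + (1 - wgt[i])
    W[i, j0[i] + 1] <- W[i, j0[i] + 1] + wgt[i]
  }
  W
}

resample_matrix <- function(V, size) {
  n <- nrow(V)
  if (n == size) return(V)
  W <- bilinear_matrix(n, size)
  W %*% V %*% t(W)
}

new_cos_image <- function(pixels, kind, sample_id, label) {
  structure(
    list(pixels = pixels, kind = kind, sample_id = sample_id, label = label),
    class = "cos_image"
  )
}

#' @export
print.cos_image <- function(x, ...) {
  cat(sprintf("<cos_image %s: %dx%dx3, sample '%s', label %s>\n",
              x$kind, dim(x$pixels)[1], dim(x$pixels)[2],
              x$sample_id, x$label))
  invisible(x)
}

check_size <- function(size) {
  if (!is.numeric(size) || size < 8) {
    stop_parameter("`size` must be at least 8 pixels.")
  }
  as.integer(size)
}

#' Render a 1D spectrum curve
#'
#' Draws the absorbance curve (wavenumber descending left to right, per FT-IR
#' convention) as a black polyline on white, with per-image min-max vertical
#' scaling and no axes, ticks or text.
#'
#' @param spectrum A one-row `mir_collection` or numeric absorbance vector.
#' @param size Output raster side length in pixels (>= 8).
#' @return A `cos_image` (`size` x `size` x 3 integer array, 0-255).
#' @export
render_1d <- function(spectrum, size = 64) {
  size <- check_size(size)
  if (inherits(spectrum, "mir_collection")) {
    a <- spectrum$absorbance[[1]]
    sid <- spectrum$sample_id[1]
    lab <- spectrum$label[1]
  } else {
    a <- as.numeric(spectrum)
    sid <- "sample"
    lab <- NA_integer_
  }
  n <- length(a)
  if (n < 1) stop_parameter("Empty spectrum.")
  rng <- range(a)
  y01 <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
  # pixel row 1 = top; margin of one pixel so extremes stay inside
  row <- 1L + as.integer(round((1 - y01) * (size - 1)))
  col <- pmin(size, 1L + as.integer(floor((seq_len(n) - 0.5) / n * size)))
  canvas <- matrix(255L, size, size)
  prev <- row[1]
  for (cix in seq_len(size)) {
    pts <- row[col == cix]
    if (!length(pts)) pts <- prev
    lo <- min(pts, prev)
    hi <- max(pts, prev)
    canvas[lo:hi, cix] <- 0L
    prev <- pts[length(pts)]
  }
  px <- array(canvas, dim = c(size, size, 3))
  new_cos_image(px, "1D", sid, lab)
}

# Shared colormapping for 2D/3D: normalize by max|value|, map to palette.
values_to_rgb <- function(u_mat, size) {
  idx <- palette_index(u_mat)
  pal <- cos_palette()
  px <- array(0L, dim = c(size, size, 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(pal[idx, ch], size, size)
  }
  px
}

#' Render a correlation map as a 2D heatmap
#'
#' Bilinearly resamples the map to `size` x `size` and applies a fixed
#' diverging colormap with colour limits symmetric about zero at
#' +/- max|value| of this map. An all-zero map renders as the uniform
#' midpoint colour.
#'
#' @param map A `cos_map`.
#' @param size Output side length in pixels.
#' @return A `cos_image` with `kind` one of `sync2D`/`async2D`/`int2D`.
#' @export
render_2d <- function(map, size = 64) {
  size <- check_size(size)
  V <- map$values
  if (!all(is.finite(V)) || nrow(V) != ncol(V)) {
    stop_parameter("Correlation map must be square and finite.")
  }
  lim <- max(abs(V))
  u <- if (lim > 0) V / lim else V
  R <- resample_matrix(u, size)
  R <- pmin(pmax(R, -1), 1)
  kind <- switch(map$kind, synchronous = "sync2D", asynchronous = "async2D",
                 integrative = "int2D", "sync2D")
  new_cos_image(values_to_rgb(R, size), kind, map$sample_id, NA_integer_)
}

#' Render a correlation map as a 3D surface projection
#'
#' Downsamples the map to a `grid_n` x `grid_n` height field, projects
#' z = value orthographically from a frozen viewpoint (azimuth 45 deg,
#' elevation 30 deg), paints cells back-to-front, and colours the surface by
#' z with the same symmetric limits as [render_2d()]. Background is white.
#'
#' @inheritParams render_2d
#' @param grid_n Surface grid resolution before projection.
#' @param azimuth,elevation Viewpoint in degrees (frozen defaults).
#' @return A `cos_image` with `kind` one of `sync3D`/`async3D`/`int3D`.
#' @export
render_3d <- function(map, size = 64, grid_n = 48, azimuth = 45,
                      elevation = 30) {
  size <- check_size(size)
  V <- map$values
  if (!all(is.finite(V)) || nrow(V) != ncol(V)) {
    stop_parameter("Correlation map must be square and finite.")
  }
  lim <- max(abs(V))
  u <- if (lim > 0) V / lim else V
  g <- min(grid_n, nrow(u))
  Z <- resample_matrix(u, g)
  Z <- pmin(pmax(Z, -1), 1)
  zbuf <- surface_raster_cpp(Z, size, azimuth * pi / 180, elevation * pi / 180,
                             0.35)
  px <- array(255L, dim = c(size, size, 3))
  hit <- is.finite(zbuf)
  idx <- palette_index(zbuf[hit])
  pal <- cos_palette()
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[hit] <- pal[idx, ch]
    px[, , ch] <- plane
  }
  kind <- switch(map$kind, synchronous = "sync3D", asynchronous = "async3D",
                 integrative = "int3D", "sync3D")
  new_cos_image(px, kind, map$sample_id, NA_integer_)
}

#' Render all seven image kinds for one sample
#'
#' @param spectrum One-row `mir_collection` (averaged, truncated).
#' @param maps `sync`/`async`/`integ` triple from [sample_cos_maps()].
#' @param size Raster side length.
#' @return Named list of 7 `cos_image`s keyed by dimension kind.
#' @export
render_sample <- function(spectrum, maps, size = 64) {
  lab <- spectrum$label[1]
  imgs <- list(
    `1D` = render_1d(spectrum, size),
    sync2D = render_2d(maps$sync, size),
    async2D = render_2d(maps$async, size),
    int2D = render_2d(maps$integ, size),
    sync3D = render_3d(maps$sync, size),
    async3D = render_3d(maps$async, size),
    int3D = render_3d(maps$integ, size)
  )
  for (k in names(imgs)) imgs[[k]]$label <- lab
  imgs
}

#' Batch-generate the spectral-image dataset
#'
#' Writes the seven PNG images per sample into
#' `out_dir/<dimension_kind>/<class_name>/<sample_id>.png` and returns the
#' manifest. Correlation maps are computed per sample (streaming) unless a
#' precomputed `maps` list is supplied.
#'
#' @param collection Preprocessed `mir_collection` (one spectrum per sample).
#' @param out_dir Output directory.
#' @param maps Optional list from [transform_collection()]; by default maps
#'   are computed on the fly against `reference`.
#' @param reference Optional class-mean list (see [transform_collection()]).
#' @param size Raster side length.
#' @param split Optional `dataset_split` (see [kennard_stone()]) used to fill
#'   the manifest's `split_role`.
#' @return Tibble manifest: `path`, `sample_id`, `label`, `dimension_kind`,
#'   `split_role`.
#' @export
batch_generate <- function(collection, out_dir, maps = NULL, reference = NULL,
                           size = 64, split = NULL) {
  if (is.null(maps)) reference <- reference %||% class_mean_spectra(collection)
  w <- wavenumbers(collection)
  roles <- split_roles(split, collection$sample_id)
  records <- vector("list", nrow(collection) * 7L)
  nrec <- 0L
  for (i in seq_len(nrow(collection))) {
    sid <- collection$sample_id[i]
    trip <- if (!is.null(maps)) {
      if (is.null(maps[[sid]])) {
        stop_parameter(sprintf("Supplied maps do not cover sample '%s'.", sid))
      }
      maps[[sid]]
    } else {
      key <- as.character(collection$label[i])
      if (is.null(reference[[key]])) {
        stop_parameter(sprintf("No reference mean for class %s.", key))
      }
      sample_cos_maps(reference[[key]], collection$absorbance[[i]],
                      wavenumber = w, sample_id = sid)
    }
    imgs <- render_sample(collection[i, ], trip, size)
    for (kind in names(imgs)) {
      dir <- file.path(out_dir, kind, collection$class_name[i])
      if (!dir.exists(dir) &&
          !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
        abort(sprintf("Cannot create image directory '%s'.", dir),
              class = "cosid_io_error",
              manifest = dplyr::bind_rows(records[seq_len(nrec)]))
      }
      path <- file.path(dir, paste0(sid, ".png"))
      ok <- tryCatch({
        png::writePNG(imgs[[kind]]$pixels / 255, path)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        abort(sprintf("Failed to write '%s'.", path),
              class = "cosid_io_error",
              manifest = dplyr::bind_rows(records[seq_len(nrec)]))
      }
      nrec <- nrec + 1L
      records[[nrec]] <- tibble(
        path = path, sample_id = sid, label = collection$label[i],
        dimension_kind = kind, split_role = roles[[sid]]
      )
    }
  }
  dplyr::bind_rows(records)
}

split_roles <- function(split, sample_ids) {
  roles <- stats::setNames(rep(NA_character_, length(sample_ids)), sample_ids)
  if (!is.null(split)) {
    roles[split$train_ids] <- "train"
    roles[split$test_ids] <- "test"
  }
  as.list(roles)
}

#' Render a collection into in-memory image arrays
#'
#' Training-oriented counterpart of [batch_generate()]: returns, per image
#' kind, a `size x size x 3 x n_samples` numeric array scaled to `[0, 1]`
#' (sample order = collection order).
#'
#' @inheritParams batch_generate
#' @param kinds Which of the seven kinds to render.
#' @return Named list of 4-d arrays plus attributes `sample_id`, `label`.
#' @export
render_image_arrays <- function(collection, reference = NULL, size = 64,
                                kinds = IMAGE_KINDS) {
  reference <- reference %||% class_mean_spectra(collection)
  w <- wavenumbers(collection)
  n <- nrow(collection)
  out <- lapply(kinds, function(k) array(0, dim = c(size, size, 3, n)))
  names(out) <- kinds
  for (i in seq_len(n)) {
    key <- as.character(collection$label[i])
    trip <- sample_cos_maps(reference[[key]], collection$absorbance[[i]],
                            wavenumber = w,
                            sample_id = collection$sample_id[i])
    imgs <- render_sample(collection[i, ], trip, size)
    for (k in kinds) out[[k]][, , , i] <- imgs[[k]]$pixels / 255
  }
  for (k in kinds) {
    attr(out[[k]], "sample_id") <- collection$sample_id
    attr(out[[k]], "label") <- collection$label
  }
  out
}
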