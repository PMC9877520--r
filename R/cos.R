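# Two-dimensional correlation spectroscopy core: the perturbation matrix,
# the Hilbert-Noda matrix, and the synchronous / asynchronous / integrative
# correlation maps.
#
# With a perturbation matrix P (m x n; rows = perturbation steps, columns =
# wavenumbers) the maps are
#   synchronous   Phi = P' P / (m - 1)          (symmetric)
#   asynchronous  Psi = P' N P / (m - 1)        (antisymmetric, zero diagonal)
#   integrative   I   = Phi * Psi  elementwise  (antisymmetric, zero diagonal)
# where N is the Hilbert-Noda matrix. In the identification pipeline m = 2:
# row 1 is the class mean spectrum, row 2 the individual sample spectrum,
# used raw (no column mean-centering; with m = 2, centering would force the
# asynchronous map to vanish identically, contradicting the nonzero
# asynchronous cross-peaks this construction is meant to expose).

#' Hilbert-Noda matrix
#'
#' The antisymmetric m x m matrix with zeros on the diagonal and
#' `N[j, k] = 1 / (pi * (k - j))` off it; it effects the discrete Hilbert
#' transform in the asynchronous correlation map.
#'
#' @param m Number of perturbation steps (>= 1).
#' @return m x m numeric matrix.
#' @export
#' @examples
#' hilbert_noda(2) # [[0, 1/pi], [-1/pi, 0]]
hilbert_noda <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop_parameter("`m` must be a positive integer.")
  }
  m <- as.integer(m)
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  n <- ifelse(jk == 0, 0, 1 / (pi * jk))
  matrix(n, m, m)
}

#' Build the two-row perturbation matrix
#'
#' Stacks the class mean spectrum (first row) over one sample spectrum
#' (second row). Both must share the same (already truncated) grid.
#'
#' @param mean_spectrum,sample_spectrum One-row `mir_collection`s, or numeric
#'   vectors (then `wavenumber` must be supplied).
#' @param wavenumber Grid, required when bare numeric vectors are given.
#' @param sample_id Identifier carried into downstream maps.
#' @return A `perturbation_matrix`: list with `P` (2 x n matrix),
#'   `wavenumber`, `sample_id`.
#' @export
build_perturbation_matrix <- function(mean_spectrum, sample_spectrum,
                                      wavenumber = NULL, sample_id = NULL) {
  pull <- function(x) {
    if (inherits(x, "mir_collection")) {
      stopifnot(nrow(x) == 1L)
      list(a = x$absorbance[[1]], w = wavenumbers(x), id = x$sample_id[1])
    } else {
      list(a = as.numeric(x), w = wavenumber, id = NULL)
    }
  }
  m1 <- pull(mean_spectrum)
  m2 <- pull(sample_spectrum)
  if (!is.null(m1$w) && !is.null(m2$w) &&
      !isTRUE(all.equal(m1$w, m2$w, tolerance = 1e-12))) {
    stop_grid("Mean and sample spectra are on different wavenumber grids.")
  }
  if (length(m1$a) != length(m2$a)) {
    stop_grid("Mean and sample spectra have different lengths.")
  }
  structure(
    list(
      P = rbind(m1$a, m2$a, deparse.level = 0),
      wavenumber = m1$w %||% m2$w,
      sample_id = sample_id %||% m2$id %||% "sample"
    ),
    class = "perturbation_matrix"
  )
}

as_P <- function(P) {
  if (inherits(P, "perturbation_matrix")) return(P)
  if (is.matrix(P)) {
    return(structure(list(P = P, wavenumber = NULL, sample_id = "sample"),
                     class = "perturbation_matrix"))
  }
  stop_parameter("Expected a perturbation matrix.")
}

new_cos_map <- function(values, kind, wavenumber, sample_id) {
  structure(
    list(values = values, kind = kind, wavenumber = wavenumber,
         sample_id = sample_id),
    class = "cos_map"
  )
}

#' Synchronous correlation map
#'
#' @param P A `perturbation_matrix` (or bare m x n matrix, m >= 2).
#' @return A `cos_map` of kind `"synchronous"` (n x n, symmetric).
#' @export
synchronous_map <- function(P) {
  P <- as_P(P)
  m <- nrow(P$P)
  if (m < 2) stop_parameter("Synchronous map needs m >= 2 perturbation rows.")
  new_cos_map(crossprod(P$P) / (m - 1), "synchronous", P$wavenumber, P$sample_id)
}

#' Asynchronous correlation map
#'
#' Applies the Hilbert-Noda matrix between the perturbation rows; the result
#' is antisymmetric with an exactly zero diagonal.
#'
#' @inheritParams synchronous_map
#' @return A `cos_map` of kind `"asynchronous"`.
#' @export
asynchronous_map <- function(P) {
  P <- as_P(P)
  m <- nrow(P$P)
  if (m < 2) stop_parameter("Asynchronous map needs m >= 2 perturbation rows.")
  N <- hilbert_noda(m)
  v <- crossprod(P$P, N %*% P$P) / (m - 1)
  # antisymmetrize to kill the O(eps) floating-point residue on the diagonal
  v <- (v - t(v)) / 2
  new_cos_map(v, "asynchronous", P$wavenumber, P$sample_id)
}

#' Integrative correlation map
#'
#' Elementwise product of the synchronous and asynchronous maps; inherits the
#' asynchronous map's antisymmetry and zero diagonal.
#'
#' @param sync,asyn `cos_map`s of kinds `"synchronous"` and `"asynchronous"`
#'   for the same sample and grid.
#' @return A `cos_map` of kind `"integrative"`.
#' @export
integrative_map <- function(sync, asyn) {
  if (!inherits(sync, "cos_map") || !inherits(asyn, "cos_map") ||
      sync$kind != "synchronous" || asyn$kind != "asynchronous") {
    stop_parameter("Expected one synchronous and one asynchronous cos_map.")
  }
  if (!identical(dim(sync$values), dim(asyn$values))) {
    stop_parameter("Synchronous and asynchronous maps have different shapes.")
  }
  if (!identical(sync$sample_id, asyn$sample_id)) {
    stop_parameter("Maps belong to different samples.")
  }
  new_cos_map(sync$values * asyn$values, "integrative",
              sync$wavenumber, sync$sample_id)
}

#' Correlation-map triple for one sample
#'
#' @param mean_spectrum,sample_spectrum See [build_perturbation_matrix()].
#' @inheritParams build_perturbation_matrix
#' @return Named list `sync`, `async`, `integ` of `cos_map`s.
#' @export
sample_cos_maps <- function(mean_spectrum, sample_spectrum,
                            wavenumber = NULL, sample_id = NULL) {
  P <- build_perturbation_matrix(mean_spectrum, sample_spectrum,
                                 wavenumber, sample_id)
  s <- synchronous_map(P)
  a <- asynchronous_map(P)
  list(sync = s, async = a, integ = integrative_map(s, a))
}

#' Transform a collection into per-sample correlation maps
#'
#' For every sample, builds the two-row perturbation matrix (its class mean
#' reference first, the sample second) and returns the synchronous,
#' asynchronous and integrative maps. Deterministic given its inputs.
#'
#' @param collection A preprocessed (replicate-averaged, truncated)
#'   `mir_collection`.
#' @param reference Named list of class mean absorbance vectors (names =
#'   class labels), e.g. from [class_mean_spectra()] on the training
#'   population. Default: computed from `collection` itself.
#' @return Named list (by `sample_id`) of `sync`/`async`/`integ` triples.
#' @export
transform_collection <- function(collection, reference = NULL) {
  reference <- reference %||% class_mean_spectra(collection)
  w <- wavenumbers(collection)
  out <- vector("list", nrow(collection))
  names(out) <- collection$sample_id
  for (i in seq_len(nrow(collection))) {
    key <- as.character(collection$label[i])
    if (is.null(reference[[key]])) {
      stop_parameter(sprintf(
        "No reference mean for class %s (sample '%s').",
        key, collection$sample_id[i]
      ))
    }
    out[[i]] <- sample_cos_maps(
      reference[[key]], collection$absorbance[[i]],
      wavenumber = w, sample_id = collection$sample_id[i]
    )
  }
  out
}

#' @export
print.cos_map <- function(x, ...) {
  cat(sprintf("<cos_map %s: %d x %d, sample '%s'>\n",
              x$kind, nrow(x$values), ncol(x$values), x$sample_id))
  invisible(x)
}

#' Tidy a correlation map into long format
#' @param x A `cos_map`.
#' @param ... Unused.
#' @return Tibble with `v1`, `v2` (wavenumbers or indices) and `value`.
#' @export
tidy.cos_map <- function(x, ...) {
  w <- x$wavenumber %||% seq_len(nrow(x$values))
  tibble(
    v1 = rep(w, times = length(w)),
    v2 = rep(w, each = length(w)),
    value = as.vector(x$values)
  )
}

#' Plot correlation maps and spectra
#'
#' `autoplot.cos_map()` draws the map as a diverging-colour heatmap with
#' limits symmetric about zero; `autoplot.mir_collection()` overlays the
#' spectra coloured by class.
#'
#' @param object A `cos_map` or `mir_collection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cos_map <- function(object, ...) {
  long <- tidy(object)
  lim <- max(abs(long$value))
  if (lim == 0) lim <- 1
  ggplot2::ggplot(long, ggplot2::aes(.data$v1, .data$v2, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "#FFFFFF",
                                  high = "#A50026", limits = c(-lim, lim)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "v1 (cm⁻¹)", y = "v2 (cm⁻¹)", fill = object$kind)
}
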