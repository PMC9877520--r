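# Replicate averaging, fingerprint truncation, class mean reference spectra.

#' Average replicate scans
#'
#' Collapses each sample's replicate scans into their arithmetic mean
#' spectrum, emulating repeated acquisition of one pellet.
#'
#' @param collection A `mir_collection`.
#' @return A `mir_collection` with one spectrum per `sample_id`
#'   (`replicate = 1`), labels preserved.
#' @export
average_replicates <- function(collection) {
  w <- wavenumbers(collection)
  n <- length(w)
  bad <- vapply(collection$absorbance, length, integer(1)) != n
  if (any(bad)) {
    stop_grid(sprintf(
      "Replicates of sample '%s' are not on the collection grid.",
      collection$sample_id[which(bad)[1]]
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(collection), .data$sample_id),
    label = .data$label[1],
    class_name = .data$class_name[1],
    absorbance = list(Reduce(`+`, .data$absorbance) / dplyr::n()),
    .groups = "drop"
  )
  out$replicate <- 1L
  new_mir_collection(
    out[, c("sample_id", "replicate", "label", "class_name", "absorbance")],
    w
  )
}

#' Truncate spectra to the fingerprint region
#'
#' Keeps exactly the grid points p with `low <= p <= high` (closed interval).
#' The default 1,750-400 cm^-1 window is the compound-specific fingerprint
#' region used for discrimination; on the default grid it retains 338 points
#' (1,748 ... 400 cm^-1).
#'
#' @param collection A `mir_collection`.
#' @param high,low Interval bounds in cm^-1.
#' @return The truncated `mir_collection`; idempotent.
#' @export
truncate_fingerprint <- function(collection, high = 1750, low = 400) {
  if (!(low < high)) stop_parameter("`low` must be less than `high`.")
  w <- wavenumbers(collection)
  keep <- w >= low & w <= high
  if (!any(keep)) {
    stop_parameter(sprintf(
      "Interval [%g, %g] cm^-1 retains no grid points (grid spans %g-%g).",
      low, high, min(w), max(w)
    ))
  }
  out <- as_tibble(collection)
  out$absorbance <- lapply(out$absorbance, function(a) a[keep])
  new_mir_collection(out, w[keep])
}

#' Per-class mean spectrum
#'
#' Pointwise mean over all spectra carrying `class_id`; this is the reference
#' (first) row of the two-row perturbation matrix.
#'
#' @param collection A `mir_collection` (typically replicate-averaged and
#'   truncated).
#' @param class_id Integer class label (0-based).
#' @return A one-row `mir_collection` labelled `class_id`, with
#'   `sample_id = "classmean_<id>"`.
#' @export
compute_class_mean <- function(collection, class_id) {
  rows <- collection$label == class_id
  if (!any(rows)) {
    stop_parameter(sprintf("No spectra with class_id %s.", class_id))
  }
  a <- Reduce(`+`, collection$absorbance[rows]) / sum(rows)
  new_mir_collection(
    tibble(
      sample_id = sprintf("classmean_%d", as.integer(class_id)),
      replicate = 1L,
      label = as.integer(class_id),
      class_name = collection$class_name[rows][1],
      absorbance = list(a)
    ),
    wavenumbers(collection)
  )
}

#' All class mean spectra
#'
#' @param collection A `mir_collection`.
#' @param classes Which class labels to compute (default: all present).
#' @return Named list of absorbance vectors, names = class labels.
#' @export
class_mean_spectra <- function(collection, classes = NULL) {
  classes <- classes %||% sort(unique(collection$label))
  out <- lapply(classes, function(k) {
    compute_class_mean(collection, k)$absorbance[[1]]
  })
  names(out) <- as.character(classes)
  out
}
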