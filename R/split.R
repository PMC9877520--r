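# Kennard-Stone train/test partitioning.

#' Train/test counts for a split ratio
#'
#' Rounds the train side half-up, e.g. `split_counts(1707, 0.7)` gives
#' 1195 / 512.
#'
#' @param n_total Total sample count (>= 2).
#' @param train_fraction Fraction in (0, 1).
#' @return Named integer vector `n_train`, `n_test`, both >= 1.
#' @export
split_counts <- function(n_total, train_fraction) {
  if (n_total < 2) stop_parameter("`n_total` must be >= 2.")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_parameter("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_train <- as.integer(floor(train_fraction * n_total + 0.5))
  n_test <- as.integer(n_total - n_train)
  if (n_train < 1 || n_test < 1) {
    stop_parameter(sprintf(
      "Split %g of %d leaves an empty side (%d train / %d test).",
      train_fraction, n_total, n_train, n_test
    ))
  }
  c(n_train = n_train, n_test = n_test)
}

#' Kennard-Stone sample selection
#'
#' Deterministic max-min-distance greedy selection: seed with the pair at
#' maximal Euclidean distance, then repeatedly add the candidate whose
#' minimum distance to the already-selected set is largest. Ties break to the
#' lowest row index. The remaining samples form the test set.
#'
#' @param features N x d numeric matrix (rows = samples).
#' @param n_train Number of training samples to select (2 <= n_train < N).
#' @return A `dataset_split`: list with integer row indices `train` and
#'   `test` (both in selection/original order respectively) and
#'   `train_fraction`.
#' @export
kennard_stone <- function(features, n_train) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop_parameter("Features must be finite.")
  N <- nrow(features)
  if (n_train < 2 || n_train >= N) {
    stop_parameter("`n_train` must satisfy 2 <= n_train < N.")
  }
  D <- unname(as.matrix(dist(features)))

  # seed pair: maximal distance, ties to lexicographically smallest (i, j)
  mx <- max(D)
  hit <- which(D == mx, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])

  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- as.integer(which.max(mind)) # first max = lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(
    list(train = sel, test = setdiff(seq_len(N), sel),
         train_fraction = n_train / N),
    class = "dataset_split"
  )
}

#' Kennard-Stone split of a spectrum collection
#'
#' Selects on the raw (replicate-averaged, truncated) absorbance vectors.
#'
#' @param collection A `mir_collection` with one spectrum per sample.
#' @param train_fraction Fraction for the training side (counts via
#'   [split_counts()]).
#' @return A `dataset_split` with additional `train_ids` / `test_ids`
#'   sample-id character vectors.
#' @export
ks_split_collection <- function(collection, train_fraction) {
  if (anyDuplicated(collection$sample_id)) {
    stop_parameter("Collection must hold one spectrum per sample; average replicates first.")
  }
  counts <- split_counts(nrow(collection), train_fraction)
  sp <- kennard_stone(spectra_matrix(collection), counts[["n_train"]])
  sp$train_ids <- collection$sample_id[sp$train]
  sp$test_ids <- collection$sample_id[sp$test]
  sp
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d test (fraction %.3f)>\n",
              length(x$train), length(x$test), x$train_fraction))
  invisible(x)
}

#' Propagate split roles onto an image manifest
#'
#' Every image of a sample receives that sample's role, so no sample
#' straddles train and test across the seven image kinds.
#'
#' @param manifest Manifest tibble from [batch_generate()].
#' @param split A `dataset_split` carrying `train_ids` / `test_ids`.
#' @return The manifest with `split_role` filled.
#' @export
split_images <- function(manifest, split) {
  if (is.null(split$train_ids)) {
    stop_parameter("Split carries no sample ids; use ks_split_collection().")
  }
  roles <- c(
    stats::setNames(rep("train", length(split$train_ids)), split$train_ids),
    stats::setNames(rep("test", length(split$test_ids)), split$test_ids)
  )
  missing <- setdiff(unique(manifest$sample_id), names(roles))
  if (length(missing)) {
    stop_parameter(sprintf(
      "Sample '%s' in manifest has no split role.", missing[1]
    ))
  }
  manifest$split_role <- unname(roles[manifest$sample_id])
  manifest
}
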