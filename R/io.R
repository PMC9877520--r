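# Collection CSV round trip.
#
# On disk a collection is a directory with two UTF-8 CSVs:
#   spectra.csv  - first column `wavenumber_cm-1`, then one absorbance column
#                  per (sample_id, replicate), named "<sample_id>__r<rep>"
#   manifest.csv - sample_id,label,class_name,origin

#' Write a spectrum collection to a directory
#'
#' @param collection A `mir_collection`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_collection <- function(collection, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- wavenumbers(collection)
  wide <- c(
    list(`wavenumber_cm-1` = w),
    stats::setNames(
      collection$absorbance,
      sprintf("%s__r%d", collection$sample_id, collection$replicate)
    )
  )
  readr::write_csv(as_tibble(wide), file.path(path, "spectra.csv"))
  manifest <- dplyr::distinct(
    as_tibble(collection)[, c("sample_id", "label", "class_name")]
  )
  manifest$origin <- "synthetic"
  readr::write_csv(manifest, file.path(path, "manifest.csv"))
  invisible(path)
}

#' Read a spectrum collection from a directory
#'
#' Validates the format strictly: every absorbance cell must be numeric and
#' present, every spectra column must appear in the manifest, and manifest
#' labels must form the contiguous set 0..K-1. Violations raise a format
#' error naming the offending line or column.
#'
#' @param path Directory written by [write_collection()].
#' @return A `mir_collection`.
#' @export
read_collection <- function(path) {
  sp_file <- file.path(path, "spectra.csv")
  mf_file <- file.path(path, "manifest.csv")
  if (!file.exists(sp_file) || !file.exists(mf_file)) {
    stop_format(sprintf("Missing spectra.csv or manifest.csv under '%s'.", path))
  }
  sp <- suppressWarnings(readr::read_csv(
    sp_file,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  ))
  probs <- readr::problems(sp)
  if (nrow(probs) > 0) {
    stop_format(sprintf(
      "Malformed spectra.csv at line %d, column %d: expected %s, got '%s'.",
      probs$row[1] + 1L, probs$col[1], probs$expected[1], probs$actual[1]
    ))
  }
  if (anyNA(sp)) {
    bad <- which(is.na(sp), arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "Missing absorbance value in spectra.csv at line %d, column '%s'.",
      bad[1] + 1L, names(sp)[bad[2]]
    ))
  }
  if (names(sp)[1] != "wavenumber_cm-1") {
    stop_format("First column of spectra.csv must be 'wavenumber_cm-1'.")
  }

  mf <- readr::read_csv(
    mf_file,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      label = readr::col_integer(),
      class_name = readr::col_character(),
      origin = readr::col_character()
    ),
    progress = FALSE
  )
  labs <- sort(unique(mf$label))
  if (anyNA(mf$label) || !identical(labs, seq(0L, max(labs)))) {
    stop_format(sprintf(
      "Manifest labels must form the contiguous set 0..K-1; got {%s}.",
      paste(labs, collapse = ", ")
    ))
  }

  cols <- names(sp)[-1]
  m <- regmatches(cols, regexec("^(.*)__r([0-9]+)$", cols))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) {
    stop_format(sprintf(
      "Spectra column '%s' is not named '<sample_id>__r<replicate>'.",
      cols[bad[1]]
    ))
  }
  sample_id <- vapply(m, `[`, character(1), 2)
  replicate <- as.integer(vapply(m, `[`, character(1), 3))
  unknown <- setdiff(sample_id, mf$sample_id)
  if (length(unknown)) {
    stop_format(sprintf(
      "Spectra column references sample_id '%s' absent from manifest.",
      unknown[1]
    ))
  }
  meta <- mf[match(sample_id, mf$sample_id), ]
  new_mir_collection(
    tibble(
      sample_id = sample_id,
      replicate = replicate,
      label = meta$label,
      class_name = meta$class_name,
      absorbance = lapply(seq_along(cols), function(j) sp[[j + 1L]])
    ),
    sp[["wavenumber_cm-1"]]
  )
}
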