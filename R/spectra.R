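# Synthetic FT-MIR spectra: wavenumber grids, class band profiles, simulation.

#' Wavenumber grid for mid-infrared spectra
#'
#' Builds a strictly descending, evenly spaced wavenumber grid in cm^-1. The
#' default covers the conventional FT-MIR presentation range 4,000-400 cm^-1
#' at 4 cm^-1 spacing (901 points).
#'
#' @param high,low Grid endpoints in cm^-1 (`high > low`).
#' @param by Spacing in cm^-1 per step.
#' @return Numeric vector of wavenumbers, descending.
#' @export
#' @examples
#' length(mir_grid()) # 901
mir_grid <- function(high = 4000, low = 400, by = 4) {
  if (!(high > low) || by <= 0) {
    stop_parameter("`high` must exceed `low` and `by` must be positive.")
  }
  seq(high, low, by = -by)
}

check_grid <- function(wavenumber) {
  if (length(wavenumber) < 2L) stop_grid("Wavenumber grid needs >= 2 points.")
  d <- diff(wavenumber)
  if (any(d >= 0)) stop_grid("Wavenumber grid must be strictly descending.")
  if (max(abs(d - d[1])) > 1e-9) {
    stop_grid("Wavenumber grid spacing must be constant (within 1e-9 cm^-1).")
  }
  invisible(wavenumber)
}

# Common FT-MIR band set shared by every class: water/O-H stretch, lipid C-H
# stretches, amide I, protein/polysaccharide bending region, chitin
# carbohydrate peaks, and low-wavenumber skeletal bands.
common_bands <- function() {
  tibble(
    center = c(3342, 2928, 2855, 1650, 1420, 1080, 1032, 650, 550),
    width  = c(160,  25,   22,   45,   35,   30,   25,   40,  35),
    height = c(1.00, 0.35, 0.25, 0.90, 0.45, 0.70, 0.65, 0.30, 0.35)
  )
}

#' Default class band profiles
#'
#' Generates `n_classes` class profiles sharing the common FT-MIR band set
#' (O-H, C-H, amide I, polysaccharide and chitin bands) with class-specific,
#' reproducibly drawn height multipliers. `separation` scales the inter-class
#' height differences; any two generated profiles are guaranteed to differ by
#' at least 10% in at least one band height.
#'
#' @param n_classes Number of classes (2..64).
#' @param seed Integer seed; profiles are a pure function of
#'   `(n_classes, seed, separation)`.
#' @param separation Non-negative scalar scaling inter-class differences.
#'   The default 0.25 (band-height multipliers within +/- 8.75%) keeps the 1D
#'   absorbance curves of different classes nearly overlapping, emulating the
#'   near-indistinguishable congeneric spectra the correlation transform is
#'   meant to resolve.
#' @return Tibble with one row per class: `class_id` (0-based), `class_name`,
#'   `baseline_slope`, and a `bands` list-column of `center`/`width`/`height`
#'   tibbles.
#' @export
#' @examples
#' profs <- make_default_profiles(8, seed = 7)
#' profs$bands[[1]]
make_default_profiles <- function(n_classes, seed = 1L, separation = 0.25) {
  if (!is.numeric(n_classes) || n_classes < 2 || n_classes > 64) {
    stop_parameter("`n_classes` must be between 2 and 64.")
  }
  n_classes <- as.integer(n_classes)
  if (separation < 0) stop_parameter("`separation` must be non-negative.")
  base <- common_bands()
  nb <- nrow(base)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "profiles"))

  draw_mult <- function() 1 + separation * stats::runif(nb, -0.35, 0.35)
  mults <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    ok <- FALSE
    for (attempt in 1:100) {
      cand <- draw_mult()
      distinct <- TRUE
      if (k > 1L) {
        for (j in seq_len(k - 1L)) {
          h1 <- base$height * cand
          h2 <- base$height * mults[[j]]
          if (max(pmax(h1, h2) / pmin(h1, h2)) < 1.1) {
            distinct <- FALSE
            break
          }
        }
      }
      if (distinct) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_parameter(
        "Could not draw sufficiently distinct class profiles; increase `separation`."
      )
    }
    mults[[k]] <- cand
  }

  bands <- lapply(mults, function(m) {
    b <- base
    b$height <- b$height * m
    b
  })
  tibble(
    class_id = 0:(n_classes - 1L),
    class_name = sprintf("species_%02d", 1:n_classes),
    baseline_slope = 0,
    bands = bands
  )
}

# Save/restore .Random.seed so simulation helpers do not perturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

gaussian_bands <- function(wavenumber, bands) {
  if (any(bands$width <= 0) || any(bands$height < 0)) {
    stop_parameter("Band widths must be positive and heights non-negative.")
  }
  a <- numeric(length(wavenumber))
  for (i in seq_len(nrow(bands))) {
    a <- a + bands$height[i] *
      exp(-((wavenumber - bands$center[i])^2) / (2 * bands$width[i]^2))
  }
  a
}

#' Simulate one absorbance spectrum
#'
#' Absorbance is the sum of the profile's Gaussian bands, a linear baseline,
#' and (when `noise_sd > 0`) i.i.d. Gaussian replicate-scan noise plus a small
#' random baseline-tilt jitter emulating scatter drift. With `noise_sd = 0`
#' the spectrum is fully deterministic regardless of `seed`.
#'
#' @param profile One row of [make_default_profiles()] output (or a list with
#'   `class_id`, `class_name`, `baseline_slope`, `bands`).
#' @param noise_sd Noise standard deviation in absorbance units (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param wavenumber Wavenumber grid (descending, even spacing).
#' @param baseline_sd Standard deviation of the per-spectrum baseline slope
#'   jitter, in absorbance per cm^-1 (drawn only when `noise_sd > 0`).
#' @return A one-row spectrum collection (see [simulate_collection()]).
#' @export
simulate_spectrum <- function(profile, noise_sd = 0.01, seed = 1L,
                              wavenumber = mir_grid(), baseline_sd = 1e-4) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- as.list(profile)
    profile$bands <- profile$bands[[1]]
  }
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")
  check_grid(wavenumber)
  a <- gaussian_bands(wavenumber, profile$bands)
  slope <- profile$baseline_slope %||% 0
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    slope <- slope + rnorm(1, 0, baseline_sd)
    a <- a + rnorm(length(a), 0, noise_sd)
  }
  a <- a + slope * (wavenumber - min(wavenumber))
  new_mir_collection(
    tibble(
      sample_id = sprintf("%s_s001", profile$class_name %||% "sample"),
      replicate = 1L,
      label = as.integer(profile$class_id %||% 0L),
      class_name = as.character(profile$class_name %||% "class_0"),
      absorbance = list(a)
    ),
    wavenumber
  )
}

#' Simulate a labelled spectrum collection
#'
#' Draws `n_per_class * replicates` spectra for every class profile. Replicate
#' scans of a sample share the sample's band structure but receive independent
#' noise and baseline jitter, emulating repeated acquisition of one pellet.
#'
#' @param profiles Output of [make_default_profiles()].
#' @param n_per_class Samples per class (>= 1).
#' @param replicates Scans per sample (>= 1).
#' @param noise_sd Per-scan noise standard deviation (absorbance units).
#' @param seed Integer master seed; the collection is a pure function of its
#'   arguments.
#' @param wavenumber Wavenumber grid.
#' @return A `mir_collection`: a tibble with columns `sample_id`, `replicate`,
#'   `label`, `class_name` and a list-column `absorbance`, carrying the grid
#'   as the `wavenumber` attribute.
#' @export
#' @examples
#' coll <- simulate_collection(make_default_profiles(2), n_per_class = 3)
#' nrow(coll) # 2 * 3 * 2 replicates
simulate_collection <- function(profiles, n_per_class, replicates = 2L,
                                noise_sd = 0.01, seed = 1L,
                                wavenumber = mir_grid()) {
  if (n_per_class < 1) stop_parameter("`n_per_class` must be >= 1.")
  if (replicates < 1) stop_parameter("`replicates` must be >= 1.")
  check_grid(wavenumber)
  n_total <- nrow(profiles) * n_per_class * replicates

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "collection"))
  spectrum_seeds <- sample.int(2147483646L, n_total)

  rows <- vector("list", n_total)
  idx <- 0L
  for (k in seq_len(nrow(profiles))) {
    prof <- as.list(profiles[k, ])
    prof$bands <- prof$bands[[1]]
    for (i in seq_len(n_per_class)) {
      sid <- sprintf("%s_s%03d", prof$class_name, i)
      for (r in seq_len(replicates)) {
        idx <- idx + 1L
        sp <- simulate_spectrum(prof, noise_sd, spectrum_seeds[idx], wavenumber)
        rows[[idx]] <- tibble(
          sample_id = sid,
          replicate = as.integer(r),
          label = as.integer(prof$class_id),
          class_name = prof$class_name,
          absorbance = sp$absorbance
        )
      }
    }
  }
  new_mir_collection(dplyr::bind_rows(rows), wavenumber)
}

# collection container --------------------------------------------------------

#' Construct a spectrum collection
#'
#' @param df Tibble with columns `sample_id`, `replicate`, `label`,
#'   `class_name`, `absorbance` (list of numeric vectors).
#' @param wavenumber Shared wavenumber grid.
#' @return The tibble, classed `mir_collection`, with the grid attached.
#' @export
new_mir_collection <- function(df, wavenumber) {
  check_grid(wavenumber)
  df <- as_tibble(df)
  needed <- c("sample_id", "replicate", "label", "class_name", "absorbance")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_format(paste0("Collection lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  len_ok <- vapply(df$absorbance, function(a) {
    length(a) == length(wavenumber) && all(is.finite(a))
  }, logical(1))
  if (!all(len_ok)) {
    stop_format(sprintf(
      "Spectrum %d has wrong length or non-finite absorbance.",
      which(!len_ok)[1]
    ))
  }
  if (anyDuplicated(paste(df$sample_id, df$replicate))) {
    stop_format("Duplicate (sample_id, replicate) pairs in collection.")
  }
  attr(df, "wavenumber") <- as.numeric(wavenumber)
  class(df) <- unique(c("mir_collection", class(df)))
  df
}

#' Wavenumber grid of a collection
#' @param x A `mir_collection`.
#' @return Numeric vector of wavenumbers (cm^-1), descending.
#' @export
wavenumbers <- function(x) {
  w <- attr(x, "wavenumber")
  if (is.null(w)) stop_grid("Object carries no wavenumber grid.")
  w
}

#' Absorbance matrix of a collection
#'
#' @param x A `mir_collection`.
#' @return Numeric matrix, one row per spectrum (rownames
#'   `sample_id.replicate`), one column per wavenumber.
#' @export
spectra_matrix <- function(x) {
  m <- do.call(rbind, x$absorbance)
  rownames(m) <- paste(x$sample_id, x$replicate, sep = ".")
  colnames(m) <- NULL
  m
}

#' @export
`[.mir_collection` <- function(x, ...) {
  w <- attr(x, "wavenumber")
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("sample_id", "absorbance") %in% names(out))) {
    attr(out, "wavenumber") <- w
    class(out) <- unique(c("mir_collection", class(out)))
  }
  out
}

#' @export
print.mir_collection <- function(x, ...) {
  w <- wavenumbers(x)
  cat(sprintf(
    "<mir_collection: %d spectra, %d samples, %d classes, %g-%g cm^-1 (%d pts)>\n",
    nrow(x), length(unique(x$sample_id)), length(unique(x$label)),
    max(w), min(w), length(w)
  ))
  NextMethod()
}

#' @rdname autoplot.cos_map
#' @export
autoplot.mir_collection <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber, y = .data$absorbance,
    group = interaction(.data$sample_id, .data$replicate),
    colour = .data$class_name
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Wavenumber (cm⁻¹)", y = "Absorbance",
                  colour = "Class")
}

#' Tidy a spectrum collection into long format
#' @param x A `mir_collection`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `replicate`, `label`, `class_name`,
#'   `wavenumber`, `absorbance`.
#' @export
tidy.mir_collection <- function(x, ...) {
  w <- wavenumbers(x)
  tidyr::unnest_longer(
    dplyr::mutate(as_tibble(x), wavenumber = list(w)),
    c("wavenumber", "absorbance")
  )
}
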