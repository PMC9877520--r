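# One-command orchestration: simulate -> preprocess -> transform -> render ->
# split -> train -> report.

#' Pipeline configuration
#'
#' All seeds derive from `seed` via named substreams, so a re-run with the
#' same config reproduces every split, image and comparison row.
#'
#' @param n_classes,n_per_class,replicates,noise_sd,separation Simulation
#'   block (see [simulate_collection()], [make_default_profiles()]).
#' @param fingerprint `c(high, low)` truncation bounds in cm^-1.
#' @param image_size Raster side length.
#' @param svm_fraction,cnn_fraction Kennard-Stone train fractions for the
#'   SVM (8:2) and the CNNs (7:3).
#' @param svm SVM block: `c_grid`, `g_grid`, `folds`.
#' @param alexnet,resnet [cnn_config()] overrides (lists).
#' @param methods Subset of `c("svm", "alexnet", "resnet")` to run.
#' @param kinds Image kinds for the CNNs (default all seven).
#' @param write_images Write the PNG tree (otherwise images stay in memory).
#' @param keep_models Retain full trained networks in the returned fits.
#'   Off by default: a run trains 14 CNNs and keeping every parameter array
#'   costs gigabytes; metrics, curves and confusion matrices are always kept.
#' @param seed Root seed.
#' @return A `cosid_config` list.
#' @export
cosid_config <- function(n_classes = 8L, n_per_class = 25L, replicates = 2L,
                         noise_sd = 0.01, separation = 0.25,
                         fingerprint = c(1750, 400), image_size = 64L,
                         svm_fraction = 0.8, cnn_fraction = 0.7,
                         svm = list(c_grid = 2^seq(-5, 21, by = 2),
                                    g_grid = 2^seq(-15, 3, by = 2),
                                    folds = 5L),
                         alexnet = list(dense_units = 1024L),
                         resnet = list(),
                         methods = c("svm", "alexnet", "resnet"),
                         kinds = IMAGE_KINDS,
                         write_images = TRUE, keep_models = FALSE,
                         seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  kinds <- match.arg(kinds, IMAGE_KINDS, several.ok = TRUE)
  structure(
    list(n_classes = as.integer(n_classes),
         n_per_class = as.integer(n_per_class),
         replicates = as.integer(replicates), noise_sd = noise_sd,
         separation = separation, fingerprint = fingerprint,
         image_size = as.integer(image_size), svm_fraction = svm_fraction,
         cnn_fraction = cnn_fraction, svm = svm, alexnet = alexnet,
         resnet = resnet, methods = methods, kinds = kinds,
         write_images = isTRUE(write_images),
         keep_models = isTRUE(keep_models), seed = as.integer(seed)),
    class = "cosid_config"
  )
}

#' Read/write a pipeline config as YAML
#' @param config A `cosid_config`.
#' @param path YAML file path.
#' @return `read_config()` returns the `cosid_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cosid_config, raw)
}

kind_dimension <- function(kind) {
  switch(kind, `1D` = "1D", sync2D = , async2D = , int2D = "2D", "3D")
}

kind_image_type <- function(kind) {
  switch(kind, `1D` = "spectrum",
         sync2D = , sync3D = "synchronous",
         async2D = , async3D = "asynchronous",
         "integrative")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "cosid_stage_error", stage = stage, parent = e)
  })
}

#' Run the full identification pipeline
#'
#' Simulates the collection, averages replicates, truncates to the
#' fingerprint region, Kennard-Stone-splits at the SVM (default 8:2) and CNN
#' (default 7:3) ratios, renders the seven image kinds, trains the selected
#' models, and writes the run directory: collection CSVs, split CSVs, the
#' image tree (optional), `comparison.csv` and `run.json`.
#'
#' @param config A [cosid_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress.
#' @return List: `comparison` table, `fits`, `splits`, `collection`, paths.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "cosid_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: %d classes x %d samples x %d replicates",
      config$n_classes, config$n_per_class, config$replicates)
  collection <- run_stage("simulate", {
    profiles <- make_default_profiles(config$n_classes,
                                      seed = derive_seed(config$seed, "profiles"),
                                      separation = config$separation)
    coll <- simulate_collection(profiles, config$n_per_class,
                                config$replicates, config$noise_sd,
                                seed = derive_seed(config$seed, "simulate"))
    write_collection(coll, file.path(out_dir, "collection"))
    coll
  })

  prep <- run_stage("preprocess", {
    truncate_fingerprint(average_replicates(collection),
                         high = config$fingerprint[1],
                         low = config$fingerprint[2])
  })

  splits <- run_stage("split", {
    s <- list(svm = ks_split_collection(prep, config$svm_fraction),
              cnn = ks_split_collection(prep, config$cnn_fraction))
    for (nm in names(s)) {
      readr::write_csv(
        tibble(sample_id = c(s[[nm]]$train_ids, s[[nm]]$test_ids),
               role = rep(c("train", "test"),
                          c(length(s[[nm]]$train_ids), length(s[[nm]]$test_ids)))),
        file.path(out_dir, paste0("split_", nm, ".csv"))
      )
    }
    s
  })

  fits <- list()
  results <- list()

  if ("svm" %in% config$methods) {
    say("svm: grid search over %d x %d grid",
        length(config$svm$c_grid), length(config$svm$g_grid))
    fits$svm <- run_stage("svm", {
      X <- spectra_matrix(prep)
      tr <- splits$svm$train
      te <- splits$svm$test
      gs <- svm_grid_search(X[tr, , drop = FALSE], prep$label[tr],
                            c_grid = config$svm$c_grid,
                            g_grid = config$svm$g_grid,
                            folds = config$svm$folds)
      svm_train_eval(X[tr, , drop = FALSE], prep$label[tr],
                     X[te, , drop = FALSE], prep$label[te],
                     cost = gs$best_c, gamma = gs$best_g,
                     cv_accuracy = gs$cv_accuracy)
    })
    results[[length(results) + 1L]] <- list(
      method = "SVM", dimension = "1D", image_kind = "spectrum",
      fit = fits$svm
    )
  }

  cnn_methods <- intersect(config$methods, c("alexnet", "resnet"))
  if (length(cnn_methods)) {
    say("render: %d kinds x %d samples", length(config$kinds), nrow(prep))
    imgs <- run_stage("render", {
      # class-mean references from the CNN training population only, so no
      # test-set information leaks into the reference spectra
      train_prep <- prep[prep$sample_id %in% splits$cnn$train_ids, ]
      reference <- class_mean_spectra(train_prep,
                                      classes = sort(unique(prep$label)))
      if (config$write_images) {
        manifest <- batch_generate(prep, file.path(out_dir, "images"),
                                   reference = reference,
                                   size = config$image_size,
                                   split = splits$cnn)
        readr::write_csv(manifest, file.path(out_dir, "image_manifest.csv"))
      }
      render_image_arrays(prep, reference = reference,
                          size = config$image_size, kinds = config$kinds)
    })
    tr_idx <- match(splits$cnn$train_ids, prep$sample_id)
    te_idx <- match(splits$cnn$test_ids, prep$sample_id)
    y <- prep$label
    for (method in cnn_methods) {
      arch <- if (method == "alexnet") "alexnet" else "resnet12"
      overrides <- config[[method]]
      for (kind in config$kinds) {
        say("train: %s on %s", method, kind)
        fit <- run_stage(paste0("train_", method, "_", kind), {
          cfg <- do.call(cnn_config, c(
            list(architecture = arch, n_classes = config$n_classes,
                 seed = derive_seed(config$seed, paste0(method, "_", kind))),
            overrides
          ))
          a <- imgs[[kind]]
          train_cnn(a[, , , tr_idx, drop = FALSE], y[tr_idx],
                    a[, , , te_idx, drop = FALSE], y[te_idx], cfg,
                    verbose = verbose)
        })
        if (!config$keep_models) fit$net <- NULL
        fits[[paste(method, kind, sep = "_")]] <- fit
        results[[length(results) + 1L]] <- list(
          method = if (method == "alexnet") "Alexnet" else "Resnet",
          dimension = kind_dimension(kind),
          image_kind = kind_image_type(kind), fit = fit
        )
      }
    }
  }

  comparison <- run_stage("report", {
    cmp <- build_comparison(results)
    readr::write_csv(as_tibble(cmp), file.path(out_dir, "comparison.csv"))
    jsonlite::write_json(
      list(
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        seed = config$seed,
        n_samples = length(unique(collection$sample_id)),
        n_rows = nrow(cmp),
        r_version = as.character(getRversion()),
        package_version = as.character(utils::packageVersion("cosid"))
      ),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA
    )
    cmp
  })

  invisible(list(comparison = comparison, fits = fits, splits = splits,
                 collection = collection, preprocessed = prep,
                 out_dir = out_dir))
}
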