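test_that("alexnet realizes the published layer schedule", {
  net <- build_alexnet(8, dense_units = 32)
  trace <- net_shape_trace(net)
  pools <- trace$shape[trace$kind == "maxpool"]
  expect_equal(pools, c("32x32x96x1", "16x16x256x1", "8x8x256x1"))
  convs <- trace$shape[trace$kind == "conv"]
  expect_equal(convs, c("64x64x96x1", "32x32x256x1", "16x16x384x1",
                        "16x16x384x1", "16x16x256x1"))
  # default head widths follow the published 4096/4096/K schedule
  full <- build_alexnet(8)
  dense_dims <- vapply(
    Filter(function(l) l$kind == "dense", full$layers),
    function(l) nrow(l$params$W), integer(1)
  )
  expect_equal(dense_dims, c(4096L, 4096L, 8L))
  expect_error(build_alexnet(1), class = "cosid_parameter_error")
})

test_that("alexnet probabilities are a valid softmax on any input", {
  net <- build_alexnet(5, dense_units = 16)
  imgs <- array(0, c(64, 64, 3, 2))
  pred <- predict(net, imgs)
  expect_true(all(is.finite(pred$prob)))
  expect_equal(rowSums(pred$prob), c(1, 1), tolerance = 1e-6)
})

test_that("resnet12 has 12 weight layers as 3 identity + 2 projection blocks", {
  net <- build_resnet12(8)
  expect_equal(count_weight_layers(net), 12L)
  expect_equal(block_census(net), c(identity = 3L, projection = 2L))
  set.seed(1)
  imgs <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  pred <- predict(net, imgs)
  expect_equal(rowSums(pred$prob), rep(1, 3), tolerance = 1e-6)
  expect_identical(predict(net, imgs)$labels, pred$labels)
  expect_error(predict(net, array(0, c(32, 32, 3, 1))),
               class = "cosid_parameter_error")
})

test_that("the early-stopping rule reproduces its worked trace", {
  r <- early_stopping_trace(c(0.50, 0.60, 0.60, 0.60, 0.60, 0.60, 0.60),
                            patience = 5, min_delta = 0.001)
  expect_equal(r$stop_epoch, 7)
  expect_equal(r$best_epoch, 2)
  # strictly improving trace never triggers
  r2 <- early_stopping_trace(seq(0.1, 0.9, by = 0.1), patience = 5,
                             min_delta = 0.001)
  expect_true(is.na(r2$stop_epoch))
  expect_equal(r2$best_epoch, 9)
  # stop - best never exceeds patience
  set.seed(8)
  for (i in 1:50) {
    tr <- runif(sample(3:20, 1))
    r <- early_stopping_trace(tr, patience = 3, min_delta = 0.01)
    if (!is.na(r$stop_epoch)) {
      expect_lte(r$stop_epoch - r$best_epoch, 3)
    }
  }
})

test_that("SVM grid search separates Gaussian blobs and breaks ties stably", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40 * 5, 0), 40, 5), matrix(rnorm(40 * 5, 4), 40, 5))
  y <- rep(0:1, each = 40)
  gs <- svm_grid_search(x, y, c_grid = 2^c(-1, 3, 7), g_grid = 2^c(-7, -3),
                        folds = 3)
  expect_gte(gs$cv_accuracy, 0.95)
  one <- svm_grid_search(x, y, c_grid = 2, g_grid = 0.125, folds = 3)
  expect_equal(one$best_c, 2)
  expect_equal(one$best_g, 0.125)
  dup <- svm_grid_search(x, y, c_grid = c(2, 2, 2), g_grid = c(0.125, 0.125),
                         folds = 3)
  expect_equal(c(dup$best_c, dup$best_g), c(one$best_c, one$best_g))
  expect_error(svm_grid_search(x, rep(0, 80), folds = 3),
               class = "cosid_parameter_error")
})

test_that("the svm fit reports confusion-level metrics", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30 * 4, 0), 30, 4), matrix(rnorm(30 * 4, 5), 30, 4))
  y <- rep(0:1, each = 30)
  te <- c(1:5, 31:35)
  fit <- svm_train_eval(x[-te, ], y[-te], x[te, ], y[te], cost = 4, gamma = 0.1)
  expect_equal(sum(fit$confusion), 10)
  expect_gte(fit$accuracy, 0.9)
  expect_length(fit$sensitivity, 2)
})

test_that("a separable two-class image problem trains to perfect accuracy", {
  # visually disjoint synchronous maps: high separation, no replicate noise
  profs <- make_default_profiles(2, seed = 2, separation = 2)
  coll <- simulate_collection(profs, 30, 1, noise_sd = 0, seed = 1)
  prep <- truncate_fingerprint(coll)
  imgs <- render_image_arrays(prep, kinds = "sync2D")$sync2D
  lab <- prep$label
  # manual stratified 40/20 split (KS degenerates on identical duplicates)
  tr <- c(1:20, 31:50)
  te <- setdiff(seq_len(60), tr)
  cfg <- cnn_config("resnet12", n_classes = 2, epochs = 30, seed = 5,
                    early_stopping = list(min_delta = 0.001, patience = 5))
  fit <- train_cnn(imgs[, , , tr, drop = FALSE], lab[tr],
                   imgs[, , , te, drop = FALSE], lab[te], cfg)
  expect_equal(fit$accuracy, 1.0)
  expect_lte(fit$stopping_epoch, 30)
  # converged separable run: zero training errors
  pred_tr <- predict(fit, imgs[, , , tr, drop = FALSE])
  expect_equal(mean(pred_tr$labels == lab[tr]), 1.0)
  # early stopping bookkeeping holds on the recorded curves
  expect_lte(fit$stopping_epoch - fit$best_epoch, 5)
})

test_that("training is reproducible from its seeds", {
  profs <- make_default_profiles(2, seed = 2)
  coll <- simulate_collection(profs, 6, 1, noise_sd = 0.01, seed = 3)
  prep <- truncate_fingerprint(coll)
  imgs <- render_image_arrays(prep, kinds = "sync2D")$sync2D
  lab <- prep$label
  tr <- c(1:4, 7:10)
  te <- setdiff(seq_len(12), tr)
  cfg <- cnn_config("resnet12", n_classes = 2, epochs = 2, seed = 9)
  f1 <- train_cnn(imgs[, , , tr, drop = FALSE], lab[tr],
                  imgs[, , , te, drop = FALSE], lab[te], cfg)
  f2 <- train_cnn(imgs[, , , tr, drop = FALSE], lab[tr],
                  imgs[, , , te, drop = FALSE], lab[te], cfg)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$confusion, f2$confusion)
})
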