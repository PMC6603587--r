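test_that("config validation enforces the 7-layer CNN structure", {
  expect_s3_class(classifier_config("cnn"), "classifier_config")
  expect_s3_class(classifier_config("mlp"), "classifier_config")
  bad <- list(list(type = "conv", filters = 8L),
              list(type = "fc", units = 4L))
  expect_error(classifier_config("cnn", layer_spec = bad),
               class = "csvd_config_error")
  bad_last <- classifier_config("cnn")$layer_spec
  bad_last[[7]]$units <- 5L
  expect_error(classifier_config("cnn", layer_spec = bad_last),
               class = "csvd_config_error")
  expect_error(classifier_config("cnn", epochs = 0),
               class = "csvd_config_error")
})

test_that("built models produce normalized softmax output of length 4", {
  set.seed(20)
  X <- matrix(runif(50 * 49, 0, 255), 50, 49)
  for (kind in c("cnn", "mlp")) {
    m <- build_classifier(classifier_config(kind, seed = 5))
    expect_gt(m$n_parameters, 0)
    pred <- predict_patches(m, X)
    expect_equal(dim(pred$prob), c(50L, 4L))
    expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
    expect_true(all(pred$prob >= 0 & pred$prob <= 1))
    expect_true(all(pred$class %in% 0:3))
  }
  # identical inputs give identical outputs (pure function)
  m <- build_classifier(classifier_config("cnn", seed = 5))
  dup <- rbind(X[1, ], X[1, ])
  p <- predict_patches(m, dup)
  expect_identical(p$prob[1, ], p$prob[2, ])
  expect_error(predict_patches(m, matrix(0, 2, 25)),
               class = "csvd_shape_error")
})

test_that("convolution layers agree with a direct sliding-window oracle", {
  # single valid 3x3 convolution, weights set by hand
  cfg <- classifier_config("cnn", seed = 2)
  m <- build_classifier(cfg)
  l1 <- m$layers[[1]]
  set.seed(21)
  x <- matrix(runif(49), 7, 7)            # one sample, spatial form
  X <- matrix(as.vector(t(x)), 1, 49)     # row-major flat
  out <- csvdseg:::nn_forward(m$layers[1], X)$out
  # oracle: direct loop over output positions and taps
  for (co in c(1L, l1$cout)) {
    W <- l1$W[, co]
    for (y0 in c(1L, 3L, 5L)) {
      for (x0 in c(2L, 4L)) {
        acc <- l1$b[co]
        q <- 0L
        for (ky in -1:1) for (kx in -1:1) {
          q <- q + 1L
          acc <- acc + W[q] * x[y0 + 1L + ky, x0 + 1L + kx]
        }
        acc <- max(acc, 0)                # ReLU
        flat <- (co - 1L) * 25L + (y0 - 1L) * 5L + x0
        expect_equal(out[1, flat], acc, tolerance = 1e-12)
      }
    }
  }
})

test_that("training gradients match finite differences", {
  cfg <- classifier_config("cnn", seed = 3)
  m <- build_classifier(cfg)
  set.seed(22)
  X <- matrix(runif(4 * 49), 4, 49)
  y <- c(0L, 1L, 2L, 3L)
  Y <- matrix(0, 4, 4); Y[cbind(1:4, y + 1L)] <- 1
  loss_of <- function(layers) {
    P <- csvdseg:::nn_softmax(csvdseg:::nn_forward(layers, X)$out)
    -sum(Y * log(P)) / 4
  }
  fwd <- csvdseg:::nn_forward(m$layers, X, want_cache = TRUE)
  P <- csvdseg:::nn_softmax(fwd$out)
  grads <- csvdseg:::nn_backward(m$layers, fwd$caches, (P - Y) / 4)
  eps <- 1e-6
  for (li in seq_along(m$layers)) {
    if (is.null(m$layers[[li]]$W)) next
    for (i in sample(length(m$layers[[li]]$W), 3)) {
      l2 <- m$layers
      l2[[li]]$W[i] <- l2[[li]]$W[i] + eps; up <- loss_of(l2)
      l2[[li]]$W[i] <- l2[[li]]$W[i] - 2 * eps; dn <- loss_of(l2)
      num <- (up - dn) / (2 * eps)
      expect_equal(grads[[li]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("seeded training is reproducible and fits separable classes", {
  # constant-0 vs constant-255 patches are linearly separable
  X <- rbind(matrix(0, 40, 49), matrix(255, 40, 49))
  y <- rep(c(0L, 1L), each = 40)
  cfg <- classifier_config("mlp", epochs = 20, batch_size = 16, seed = 7)
  m1 <- train_classifier(build_classifier(cfg), X, y)
  expect_equal(tail(m1$training_log$train_acc, 1), 1.0)
  expect_equal(nrow(m1$training_log), 20L)
  m2 <- train_classifier(build_classifier(cfg), X, y)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$training_log, m2$training_log)
  expect_error(train_classifier(build_classifier(cfg), X, rep(1L, 80)),
               class = "csvd_degenerate_data_error")
})

test_that("segment_slice masks non-brain patches and respects shapes", {
  cfg <- classifier_config("cnn", epochs = 1, seed = 1)
  m <- build_classifier(cfg)
  sl <- grayscale_slice(matrix(100, 21, 21))
  empty <- binary_mask(matrix(0L, 21, 21))
  out <- segment_slice(m, sl, empty)
  expect_true(all(out$classes == 0L))
  expect_equal(c(out$height, out$width), c(21L, 21L))
  expect_error(segment_slice(m, sl, binary_mask(matrix(0L, 10, 10))),
               class = "csvd_shape_error")
  # with a mask covering one patch, only that footprint may be nonzero
  onep <- matrix(0L, 21, 21); onep[8:14, 8:14] <- 1L
  out <- segment_slice(m, sl, binary_mask(onep))
  outside <- out$classes[onep == 0L]
  expect_true(all(outside == 0L))
})

test_that("classifier round-trips through its self-describing file", {
  X <- rbind(matrix(0, 10, 49), matrix(255, 10, 49))
  y <- rep(c(0L, 3L), each = 10)
  cfg <- classifier_config("mlp", epochs = 3, batch_size = 8, seed = 9)
  m <- train_classifier(build_classifier(cfg), X, y)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  expect_identical(m2$layers, m$layers)
  expect_identical(predict_patches(m2, X)$prob, predict_patches(m, X)$prob)
})
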