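test_that("min-max normalization maps endpoints, inverts, clips and fails on constants", {
  x <- c(-2, 0, 1, 3)
  nr <- normalize_vectors(x)
  expect_equal(nr$scaled[c(1, 4)], c(0, 1))
  expect_true(all(nr$scaled >= 0 & nr$scaled <= 1))

  const <- rep(0.5, 10)
  sc <- normalize_vectors(const, nr$params)$scaled
  expect_equal(sc, rep((0.5 + 2) / 5, 10))

  set.seed(1)
  m <- matrix(rnorm(50), 5, 10)
  nm <- normalize_vectors(m)
  back <- denormalize_vectors(nm$scaled, nm$params)
  expect_equal(back, m, tolerance = 1e-12)

  # values outside the training range are clipped on reuse
  out <- normalize_vectors(c(-10, 10), nr$params)$scaled
  expect_equal(out, c(0, 1))

  expect_error(normalize_vectors(rep(1, 5)), "degenerate")
})

test_that("model_config enforces the mirrored shrinking architecture", {
  expect_error(model_config(encoder_units = c(8L, 8L, 4L)), "decreasing")
  expect_error(model_config(encoder_units = c(16L, 8L, 4L),
                            decoder_units = c(16L, 8L, 4L)), "mirror")
  expect_error(model_config(epochs = 0), "epochs")
  cfg <- model_config()
  expect_identical(cfg$decoder_units, rev(cfg$encoder_units))
})

test_that("the compiled pass agrees with the double-precision R reference", {
  set.seed(17)
  cfg <- model_config(encoder_units = c(6L, 4L, 2L), seed = 17L)
  params <- clusterecho:::ae_init_params(cfg)
  Xb <- matrix(runif(160 * 5), 160, 5)
  ref <- clusterecho:::ae_forward(params, Xb, keep_caches = TRUE)
  cpp <- clusterecho:::.ae_pass_cpp(params$layers, params$wy, params$by,
                                    Xb, TRUE)
  expect_equal(cpp$Y, ref$Y, tolerance = 1e-5)
  gref <- clusterecho:::ae_gradients(params, Xb, ref)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)
  for (l in c(1, 3, 4, 6)) {
    expect_lt(rel(cpp$layers[[l]]$dW, gref$layers[[l]]$dW), 1e-4)
    expect_lt(rel(cpp$layers[[l]]$dU, gref$layers[[l]]$dU), 1e-4)
  }
  expect_lt(rel(cpp$dwy, gref$dwy), 1e-4)
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(23)
  cfg <- model_config(encoder_units = c(5L, 3L, 2L), seed = 23L)
  params <- clusterecho:::ae_init_params(cfg)
  Xb <- matrix(runif(160 * 2), 160, 2)
  fwd <- clusterecho:::ae_forward(params, Xb, keep_caches = TRUE)
  gr <- clusterecho:::ae_gradients(params, Xb, fwd)
  loss <- function(p) mean((clusterecho:::ae_forward(p, Xb)$Y - Xb)^2)
  eps <- 1e-6
  for (l in c(1L, 4L)) {
    idx <- sample(length(params$layers[[l]]$W), 3)
    for (j in idx) {
      p1 <- params; p1$layers[[l]]$W[j] <- p1$layers[[l]]$W[j] + eps
      p2 <- params; p2$layers[[l]]$W[j] <- p2$layers[[l]]$W[j] - eps
      gnum <- (loss(p1) - loss(p2)) / (2 * eps)
      expect_equal(gr$layers[[l]]$dW[j], gnum, tolerance = 1e-4)
    }
  }
})

test_that("training validates inputs and reproduces under a fixed seed", {
  expect_error(train_autoencoder(matrix(0, 0, 160), tiny_model()), "empty")
  expect_error(train_autoencoder(matrix(0.5, 5, 100), tiny_model()), "160")
  expect_error(train_autoencoder(matrix(2, 5, 160), tiny_model()), "0, 1")

  set.seed(3)
  X <- matrix(runif(40 * 160), 40, 160)
  m1 <- train_autoencoder(X, tiny_model(epochs = 2L, seed = 5L))
  m2 <- train_autoencoder(X, tiny_model(epochs = 2L, seed = 5L))
  expect_identical(m1$train_errors, m2$train_errors)
  expect_identical(m1$params, m2$params)

  # reconstructions always have the input length
  rec <- predict(m1, X)
  expect_identical(dim(rec), dim(X))
  expect_true(all(rec >= 0 & rec <= 1))
})

test_that("reconstruction errors equal a scalar-loop MSE oracle and are >= 0", {
  set.seed(4)
  X <- matrix(runif(10 * 160), 10, 160)
  m <- train_autoencoder(X, tiny_model(epochs = 1L, seed = 2L))
  errs <- reconstruction_errors(m, X)
  rec <- predict(m, X)
  for (i in 1:10) {
    s <- 0
    for (j in 1:160) s <- s + (X[i, j] - rec[i, j])^2
    expect_equal(errs[i], s / 160, tolerance = 1e-12)
  }
  expect_true(all(errs >= 0))
  expect_equal(reconstruction_error(m, X[3, ]), errs[3], tolerance = 1e-12)
  expect_error(reconstruction_error(m, rep(0.5, 100)), "160")
})

test_that("the threshold rule is margin times the training maximum", {
  expect_equal(compute_threshold(c(0.01, 0.02, 0.0625), margin = 1.05),
               0.065625)
  expect_equal(compute_threshold(c(0.3, 0.1), margin = 1), 0.3)
  # adding a smaller error never changes the threshold
  expect_equal(compute_threshold(c(0.3, 0.1, 0.05)), compute_threshold(c(0.3, 0.1)))
  expect_error(compute_threshold(numeric(0)), "nonempty")
  expect_error(compute_threshold(c(0.1), margin = 0.9), "margin")
  # monotone in margin
  e <- runif(10)
  expect_true(compute_threshold(e, 1.2) >= compute_threshold(e, 1.05))
})

test_that("classification is strict and monotone in the threshold", {
  set.seed(5)
  X <- matrix(runif(30 * 160), 30, 160)
  m <- train_autoencoder(X, tiny_model(epochs = 1L, seed = 7L))
  errs <- reconstruction_errors(m, X)

  # threshold exactly at the largest observed error: that vector is NOT an
  # anomaly (strict inequality)
  res <- classify(m, max(errs), X)
  expect_identical(sum(res$is_anomaly), 0L)

  res2 <- classify(m, min(errs) / 2, X)
  expect_identical(sum(res2$is_anomaly), 30L)

  # anomaly count equals a loop-counted comparison and never increases with
  # the threshold
  for (thr in stats::quantile(errs, c(0.1, 0.5, 0.9))) {
    res3 <- classify(m, thr, X)
    cnt <- 0L
    for (e in res3$error) if (e > thr) cnt <- cnt + 1L
    expect_identical(sum(res3$is_anomaly), cnt)
  }
  counts <- vapply(sort(errs), function(t2) sum(classify(m, t2, X)$is_anomaly),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("separation partitions the test set exactly by flag", {
  set.seed(6)
  X <- matrix(runif(20 * 160), 20, 160)
  m <- train_autoencoder(X, tiny_model(epochs = 1L, seed = 9L))
  errs <- reconstruction_errors(m, X)
  res <- classify(m, stats::median(errs), X)
  parts <- separate(res, X)
  expect_identical(nrow(parts$anomaly) + nrow(parts$nonanomaly), 20L)
  k_a <- 1L; k_n <- 1L
  for (i in 1:20) {
    if (res$is_anomaly[i]) {
      expect_identical(parts$anomaly[k_a, ], X[i, ]); k_a <- k_a + 1L
    } else {
      expect_identical(parts$nonanomaly[k_n, ], X[i, ]); k_n <- k_n + 1L
    }
  }

  expect_identical(nrow(separate(classify(m, max(errs), X), X)$nonanomaly), 20L)
  expect_identical(nrow(separate(classify(m, min(errs) / 2, X), X)$anomaly), 20L)
  expect_error(separate(res, X[1:5, ]), "misaligned")
})

test_that("tidiers summarize the fitted model", {
  set.seed(8)
  X <- matrix(runif(15 * 160), 15, 160)
  m <- train_autoencoder(X, tiny_model(epochs = 1L, seed = 1L))
  td <- tidy(m)
  expect_identical(nrow(td), 15L)
  gl <- glance(m)
  expect_identical(gl$n_train, 15L)
  expect_equal(gl$max_train_error, max(m$train_errors))
})
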