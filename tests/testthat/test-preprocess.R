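test_that("mean frame matches trivial cases and a scalar-loop oracle", {
  f <- matrix(3.5, 4, 6)
  expect_equal(compute_mean_frame(list(f, f, f)), f)
  expect_equal(compute_mean_frame(list(matrix(0, 2, 2), matrix(2, 2, 2))),
               matrix(1, 2, 2))
  expect_error(compute_mean_frame(list()), "empty")

  set.seed(100)
  frames <- replicate(10, matrix(rnorm(12), 3, 4), simplify = FALSE)
  m <- compute_mean_frame(frames)
  oracle <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    s <- 0
    for (k in 1:10) s <- s + frames[[k]][i, j]
    oracle[i, j] <- s / 10
  }
  expect_equal(m, oracle, tolerance = 1e-12)
})

test_that("background subtraction cancels static content", {
  f <- matrix(runif(20), 4, 5)
  out <- subtract_background(list(f, f, f), compute_mean_frame(list(f, f, f)))
  for (o in out) expect_equal(o, matrix(0, 4, 5))
  expect_equal(subtract_background(list(f), f)[[1]], matrix(0, 4, 5))
  expect_error(subtract_background(list(f), matrix(0, 2, 2)), "shape")

  set.seed(101)
  frames <- replicate(7, matrix(rnorm(24), 4, 6), simplify = FALSE)
  subbed <- subtract_background(frames, compute_mean_frame(frames))
  expect_lt(max(abs(compute_mean_frame(subbed))), 1e-10)
})

test_that("simulator clutter is fully removed by subtraction", {
  acq <- tiny_acq()
  scene <- tiny_scene(n_frames = 5L, event_prob = 0, noise_sd = 0, seed = 2L)
  ds <- simulate_dataset(acq, scene, echo_spec())
  subbed <- subtract_background(ds$frames, compute_mean_frame(ds$frames))
  for (s in subbed) expect_lt(max(abs(s)), 1e-12)
})

test_that("envelope is the analytic-signal magnitude", {
  expect_equal(envelope_image(matrix(0, 3, 64)), matrix(0, 3, 64))

  # a pure sinusoid's envelope is its amplitude away from the edges
  acq <- acquisition_spec()
  d <- 0:255
  x <- 2.5 * sin(2 * pi * acq$f0 * d / acq$fs)
  env <- envelope_image(matrix(x, 1, 256))
  interior <- 20:236
  expect_true(all(abs(env[1, interior] - 2.5) / 2.5 < 0.05))

  # magnitude of the analytic signal dominates the raw signal pointwise
  set.seed(55)
  fr <- matrix(rnorm(4 * 128), 4, 128)
  env <- envelope_image(fr)
  expect_true(all(env >= abs(fr) - 1e-9))

  # independent quadrature oracle: direct O(L^2) DFT synthesis of the
  # analytic signal, one element at a time
  L <- 32
  y <- rnorm(L)
  X <- vapply(0:(L - 1), function(k) sum(y * exp(-2i * pi * k * (0:(L - 1)) / L)),
              complex(1))
  h <- c(1, rep(2, L / 2 - 1), 1, rep(0, L / 2 - 1))
  a <- vapply(0:(L - 1), function(t2) {
    sum(h * X * exp(2i * pi * (0:(L - 1)) * t2 / L)) / L
  }, complex(1))
  expect_equal(envelope_image(matrix(y, 1, L))[1, ], Mod(a), tolerance = 1e-9)
})

test_that("ROI cropping maps indices exactly", {
  img <- matrix(seq_len(64 * 512), 64, 512)
  roi_full <- roi_spec(element_span = c(0L, 64L), depth_span = c(0L, 160L))
  expect_identical(crop_roi(img, roi_full)[, 1:160],
                   img[, 1:160])

  roi <- roi_spec(element_span = c(2L, 4L), depth_span = c(0L, 160L))
  out <- crop_roi(img, roi)
  expect_identical(dim(out), c(2L, 160L))

  roi2 <- roi_spec(element_span = c(3L, 7L), depth_span = c(20L, 180L))
  small <- matrix(rnorm(16 * 256), 16, 256)
  cropped <- crop_roi(small, roi2)
  for (i in seq_len(nrow(cropped))) for (j in seq_len(ncol(cropped))) {
    expect_identical(cropped[i, j], small[i + 3, j + 20])
  }

  expect_error(crop_roi(matrix(0, 2, 200), roi2), "bounds")
})

test_that("thresholding keeps only strict exceedances", {
  img <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(threshold_image(img, 0.5), matrix(0, 2, 2))
  pos <- matrix(runif(12) + 0.1, 3, 4)
  expect_equal(threshold_image(pos, 0), pos)
  expect_error(threshold_image(pos, -1), "nonnegative")

  set.seed(60)
  for (rep in 1:10) {
    img <- matrix(runif(48), 6, 8)
    lev <- runif(1)
    out <- threshold_image(img, lev)
    cnt <- 0L
    for (v in img) if (v > lev) cnt <- cnt + 1L
    expect_identical(sum(out != 0), cnt)
  }

  # monotonicity: raising the level never increases the retained-pixel count
  img <- matrix(runif(100), 10, 10)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(l) sum(threshold_image(img, l) != 0), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the minimum-pixel filter implements the >= 3 rule", {
  img <- matrix(0, 5, 5)
  img[1, 1] <- 1; img[2, 2] <- 1
  expect_false(has_uca(img))            # 2 nonzero pixels are not enough
  img[3, 3] <- 1
  expect_true(has_uca(img))             # 3 pixels meet the minimum
  expect_false(has_uca(matrix(0, 5, 5)))
  expect_error(has_uca(img, min_pixels = 0), "min_pixels")

  # adding nonzero pixels never flips the decision to FALSE
  base <- matrix(0, 4, 4); base[1, 1:3] <- 1
  expect_true(has_uca(base))
  base[4, 4] <- 2
  expect_true(has_uca(base))
})

test_that("center-element extraction is plain indexing", {
  roi <- roi_spec(element_span = c(2L, 6L), depth_span = c(48L, 208L))
  fr <- matrix(rnorm(8 * 256), 8, 256)
  v <- extract_center_rf(fr, roi)
  expect_length(v, 160)
  expect_identical(v, fr[roi$center_element + 1, 49:208])
  expect_equal(extract_center_rf(matrix(0, 8, 256), roi), rep(0, 160))
  expect_error(extract_center_rf(matrix(0, 4, 100), roi), "bounds")
})

test_that("roi_spec centers on the element-span midpoint, ties low", {
  expect_identical(roi_spec(c(0L, 5L), c(0L, 160L))$center_element, 2L)
  expect_identical(roi_spec(c(0L, 4L), c(0L, 160L))$center_element, 1L)
  expect_identical(roi_spec(c(10L, 11L), c(0L, 160L))$center_element, 10L)
})

test_that("dataset building retains exactly the frames a loop oracle keeps", {
  acq <- tiny_acq()
  echo <- echo_spec()
  sc_n <- tiny_scene(n_frames = 250L, cluster_frac = 0, seed = 21L)
  sc_s <- tiny_scene(n_frames = 150L, seed = 22L)
  ds_n <- simulate_dataset(acq, sc_n, echo)
  ds_s <- simulate_dataset(acq, sc_s, echo)
  roi <- tiny_roi()
  split <- build_datasets(ds_n, ds_s, roi, roi)

  # per-frame brute-force recount for the sample stack
  mean_s <- compute_mean_frame(ds_s$frames)
  kept <- logical(length(ds_s$frames))
  for (i in seq_along(ds_s$frames)) {
    env <- envelope_image(ds_s$frames[[i]] - mean_s)
    th <- threshold_image(crop_roi(env, roi), split$level_sample)
    kept[i] <- has_uca(th, split$min_pixels)
  }
  expect_identical(nrow(split$test), sum(kept))
  expect_identical(sort(split$test_info$frame_index), which(kept) - 1L)

  # no frame is shared between train and test
  expect_identical(
    nrow(dplyr::inner_join(
      dplyr::select(split$train_info, "stack", "frame_index"),
      dplyr::select(split$test_info, "stack", "frame_index"),
      by = c("stack", "frame_index"))), 0L)
  expect_false(any(split$train_info$kind %in% "cluster"))
  expect_true(all(is.finite(split$train)) && all(is.finite(split$test)))
  expect_identical(ncol(split$train), 160L)
})

test_that("frame selection is sound: retained frames carry real events", {
  acq <- tiny_acq()
  echo <- echo_spec()
  sc_n <- tiny_scene(n_frames = 600L, cluster_frac = 0, seed = 31L)
  sc_s <- tiny_scene(n_frames = 300L, seed = 32L)
  split <- build_datasets(simulate_dataset(acq, sc_n, echo),
                          simulate_dataset(acq, sc_s, echo),
                          tiny_roi(), tiny_roi())
  ret <- split$retention
  false_kept <- sum(ret$retained & ret$kind == "empty")
  expect_lt(false_kept / sum(ret$kind == "empty"), 0.01)
  kept_events <- ret$kind[ret$retained]
  expect_gt(mean(kept_events != "empty"), 0.99)
})

test_that("stacks with no events yield an explicit empty-dataset error", {
  acq <- tiny_acq()
  echo <- echo_spec()
  sc0 <- tiny_scene(n_frames = 30L, event_prob = 0, noise_sd = 0, seed = 1L)
  ds0 <- simulate_dataset(acq, sc0, echo)
  sc1 <- tiny_scene(n_frames = 30L, seed = 2L)
  ds1 <- simulate_dataset(acq, sc1, echo)
  expect_error(build_datasets(ds0, ds1, tiny_roi(), tiny_roi()),
               "empty dataset")
})
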