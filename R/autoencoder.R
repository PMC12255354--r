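#' Autoencoder model configuration
#'
#' Architecture and optimizer settings for the LSTM autoencoder. The encoder
#' is three LSTM layers with strictly decreasing widths; the decoder mirrors
#' them with increasing widths; a time-distributed single-unit sigmoid layer
#' produces the 160-sample reconstruction. Training minimizes mean squared
#' error with Adam.
#'
#' @param encoder_units Three strictly decreasing LSTM layer widths.
#' @param decoder_units Three increasing widths; must mirror the encoder.
#' @param activation Output nonlinearity; only `"sigmoid"` is supported,
#'   which is why inputs are scaled to `[0, 1]` (see [normalize_vectors()]).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling initialization and shuffling.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(encoder_units = c(32L, 16L, 8L),
                         decoder_units = rev(encoder_units),
                         activation = "sigmoid",
                         learning_rate = 1e-3, batch_size = 128L,
                         epochs = 30L, seed = 1L) {
  encoder_units <- as.integer(encoder_units)
  decoder_units <- as.integer(decoder_units)
  if (length(encoder_units) != 3 || length(decoder_units) != 3)
    stop("exactly 3 encoder and 3 decoder widths are required", call. = FALSE)
  if (any(diff(encoder_units) >= 0))
    stop("encoder widths must be strictly decreasing", call. = FALSE)
  if (!identical(decoder_units, rev(encoder_units)))
    stop("decoder widths must mirror the encoder widths", call. = FALSE)
  activation <- match.arg(activation, "sigmoid")
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0 || batch_size < 1)
    stop("learning_rate must be > 0 and batch_size >= 1", call. = FALSE)
  structure(
    list(encoder_units = encoder_units, decoder_units = decoder_units,
         activation = activation, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Min-max normalization fitted on the training set
#'
#' Scales RF amplitudes onto the `[0, 1]` range of the sigmoid output:
#' `x -> (x - lo) / (hi - lo)` with `lo`/`hi` the global minimum and maximum
#' of the training values. Fit the parameters once on the training set
#' (`params = NULL`); later calls must reuse them, and reused calls clip the
#' scaled values to `[0, 1]` so out-of-range test amplitudes saturate rather
#' than leak outside the model's output range.
#'
#' @param x Numeric matrix (n x 160) or vector of RF amplitudes.
#' @param params `NULL` to fit on `x`, or a previously fitted
#'   `normalization_params` object to reuse.
#' @return List with `scaled` (same shape as `x`) and `params`.
#' @export
normalize_vectors <- function(x, params = NULL) {
  fit <- is.null(params)
  if (fit) {
    if (length(x) == 0) stop("cannot fit normalization on empty data", call. = FALSE)
    lo <- min(x); hi <- max(x)
    if (hi <= lo)
      stop("degenerate data: all training values identical", call. = FALSE)
    params <- structure(list(lo = lo, hi = hi), class = "normalization_params")
  }
  scaled <- (x - params$lo) / (params$hi - params$lo)
  if (!fit) scaled <- pmin(pmax(scaled, 0), 1)
  list(scaled = scaled, params = params)
}

#' Invert min-max normalization
#'
#' @param scaled Scaled values.
#' @param params A `normalization_params` object.
#' @return Values on the original RF scale.
#' @export
denormalize_vectors <- function(scaled, params) {
  scaled * (params$hi - params$lo) + params$lo
}

# ---- LSTM internals ----
# The compiled pass (src/autoencoder.cpp) does the heavy lifting during
# training and scoring; the R implementations below are the readable
# reference used by the test suite to cross-check the compiled code and the
# analytic gradients.

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

lstm_init <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1   # forget-gate bias
  list(W = glorot(4 * h, d_in), U = glorot(4 * h, h), b = b)
}

# xs: list over time of d_in x n matrices. Returns hidden sequence and the
# caches backpropagation needs.
lstm_forward <- function(p, xs) {
  tt <- length(xs)
  h <- length(p$b) %/% 4L
  n <- ncol(xs[[1]])
  ri <- 1:h; rf <- (h + 1):(2 * h); rg <- (2 * h + 1):(3 * h); ro <- (3 * h + 1):(4 * h)
  hp <- matrix(0, h, n); cp <- matrix(0, h, n)
  hs <- vector("list", tt)
  I <- vector("list", tt); F_ <- vector("list", tt); G <- vector("list", tt)
  O <- vector("list", tt); TC <- vector("list", tt)
  CP <- vector("list", tt); HP <- vector("list", tt)
  for (t in seq_len(tt)) {
    z <- p$W %*% xs[[t]] + p$U %*% hp + p$b
    i <- sigmoid(z[ri, , drop = FALSE])
    f <- sigmoid(z[rf, , drop = FALSE])
    g <- tanh(z[rg, , drop = FALSE])
    o <- sigmoid(z[ro, , drop = FALSE])
    cc <- f * cp + i * g
    tc <- tanh(cc)
    I[[t]] <- i; F_[[t]] <- f; G[[t]] <- g; O[[t]] <- o; TC[[t]] <- tc
    CP[[t]] <- cp; HP[[t]] <- hp
    hp <- o * tc
    cp <- cc
    hs[[t]] <- hp
  }
  list(hs = hs, cache = list(I = I, F = F_, G = G, O = O, TC = TC,
                             CP = CP, HP = HP))
}

# dhs: list over time of gradients w.r.t. the hidden outputs (NULL = zero).
# Returns parameter gradients and the gradient w.r.t. the layer inputs.
lstm_backward <- function(p, xs, fwd, dhs) {
  tt <- length(xs)
  h <- length(p$b) %/% 4L
  n <- ncol(xs[[1]])
  ca <- fwd$cache
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, nrow(p$U), ncol(p$U))
  db <- numeric(length(p$b))
  dxs <- vector("list", tt)
  dh_next <- matrix(0, h, n); dc_next <- matrix(0, h, n)
  for (t in rev(seq_len(tt))) {
    dh <- if (is.null(dhs[[t]])) dh_next else dhs[[t]] + dh_next
    i <- ca$I[[t]]; f <- ca$F[[t]]; g <- ca$G[[t]]; o <- ca$O[[t]]
    tc <- ca$TC[[t]]
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc * tc)
    di <- dc * g
    df <- dc * ca$CP[[t]]
    dg <- dc * i
    dz <- rbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g * g), do_ * o * (1 - o))
    dW <- dW + tcrossprod(dz, xs[[t]])
    dU <- dU + tcrossprod(dz, ca$HP[[t]])
    db <- db + rowSums(dz)
    dxs[[t]] <- crossprod(p$W, dz)
    dh_next <- crossprod(p$U, dz)
    dc_next <- dc * f
  }
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

ae_init_params <- function(cfg) {
  eu <- cfg$encoder_units; du <- cfg$decoder_units
  widths_in <- c(1L, eu[1], eu[2], eu[3], du[1], du[2])
  widths_h <- c(eu, du)
  layers <- Map(lstm_init, widths_in, widths_h)
  lim <- sqrt(6 / (du[3] + 1))
  list(layers = layers,
       wy = stats::runif(du[3], -lim, lim),
       by = 0)
}

# Forward pass of the full autoencoder on a batch.
# Xb: 160 x n matrix of scaled inputs. Returns reconstruction Y (160 x n)
# and, when keep_caches = TRUE, every per-layer cache for backpropagation.
ae_forward <- function(params, Xb, keep_caches = FALSE) {
  tt <- nrow(Xb)
  xs <- lapply(seq_len(tt), function(t) Xb[t, , drop = FALSE])
  f1 <- lstm_forward(params$layers[[1]], xs)
  f2 <- lstm_forward(params$layers[[2]], f1$hs)
  f3 <- lstm_forward(params$layers[[3]], f2$hs)
  h_enc <- f3$hs[[tt]]
  xs_dec <- rep(list(h_enc), tt)
  f4 <- lstm_forward(params$layers[[4]], xs_dec)
  f5 <- lstm_forward(params$layers[[5]], f4$hs)
  f6 <- lstm_forward(params$layers[[6]], f5$hs)
  Y <- matrix(0, tt, ncol(Xb))
  for (t in seq_len(tt))
    Y[t, ] <- sigmoid(drop(crossprod(params$wy, f6$hs[[t]])) + params$by)
  out <- list(Y = Y)
  if (keep_caches)
    out <- c(out, list(xs = xs, xs_dec = xs_dec,
                       f = list(f1, f2, f3, f4, f5, f6)))
  out
}

ae_gradients <- function(params, Xb, fwd) {
  tt <- nrow(Xb); n <- ncol(Xb)
  Y <- fwd$Y
  dY <- 2 * (Y - Xb) / (tt * n)
  f6hs <- fwd$f[[6]]$hs
  dwy <- numeric(length(params$wy)); dby <- 0
  dh6 <- vector("list", tt)
  for (t in seq_len(tt)) {
    y <- Y[t, ]
    dzy <- dY[t, ] * y * (1 - y)          # 1 x n on the linear output
    dwy <- dwy + drop(f6hs[[t]] %*% dzy)
    dby <- dby + sum(dzy)
    dh6[[t]] <- params$wy %o% dzy
  }
  b6 <- lstm_backward(params$layers[[6]], fwd$f[[5]]$hs, fwd$f[[6]], dh6)
  b5 <- lstm_backward(params$layers[[5]], fwd$f[[4]]$hs, fwd$f[[5]], b6$dxs)
  b4 <- lstm_backward(params$layers[[4]], fwd$xs_dec, fwd$f[[4]], b5$dxs)
  dh_enc <- Reduce(`+`, b4$dxs)
  dh3 <- vector("list", tt)
  dh3[[tt]] <- dh_enc
  b3 <- lstm_backward(params$layers[[3]], fwd$f[[2]]$hs, fwd$f[[3]], dh3)
  b2 <- lstm_backward(params$layers[[2]], fwd$f[[1]]$hs, fwd$f[[2]], b3$dxs)
  b1 <- lstm_backward(params$layers[[1]], fwd$xs, fwd$f[[1]], b2$dxs)
  list(layers = list(b1, b2, b3, b4, b5, b6), dwy = dwy, dby = dby)
}

adam_state <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  st <- list(t = 0L)
  st$m <- lapply(params$layers, function(l) lapply(l, zero_like))
  st$v <- st$m
  st$mwy <- zero_like(params$wy); st$vwy <- st$mwy
  st$mby <- 0; st$vby <- 0
  st
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  step <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in 1:6) {
    for (nm in c("W", "U", "b")) {
      gnm <- paste0("d", nm)
      up <- step(params$layers[[l]][[nm]], grads$layers[[l]][[gnm]],
                 st$m[[l]][[nm]], st$v[[l]][[nm]])
      params$layers[[l]][[nm]] <- up$p
      st$m[[l]][[nm]] <- up$m; st$v[[l]][[nm]] <- up$v
    }
  }
  up <- step(params$wy, grads$dwy, st$mwy, st$vwy)
  params$wy <- up$p; st$mwy <- up$m; st$vwy <- up$v
  up <- step(params$by, grads$dby, st$mby, st$vby)
  params$by <- up$p; st$mby <- up$m; st$vby <- up$v
  list(params = params, state = st)
}

#' Train the LSTM autoencoder on normal RF vectors
#'
#' Fits the symmetric three-layer LSTM encoder/decoder to reconstruct
#' 160-sample, `[0, 1]`-scaled RF vectors of individual microbubbles,
#' minimizing mean squared error with Adam. The per-vector reconstruction
#' errors on the training set after the final epoch are returned alongside
#' the model; their maximum anchors the anomaly threshold
#' ([compute_threshold()]).
#'
#' @param train Numeric matrix (n x 160) of scaled training vectors in
#'   `[0, 1]`.
#' @param cfg A [model_config()].
#' @return An object of class `lstm_autoencoder`: the fitted weights, the
#'   config, per-epoch training loss, and `train_errors` (length n).
#' @export
train_autoencoder <- function(train, cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  train <- as.matrix(train)
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  if (ncol(train) != 160)
    stop("training vectors must have length 160", call. = FALSE)
  if (min(train) < -1e-9 || max(train) > 1 + 1e-9)
    stop("training values must lie in [0, 1]; normalize first", call. = FALSE)

  set.seed(cfg$seed)
  params <- ae_init_params(cfg)
  st <- adam_state(params)
  n <- nrow(train)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- t(train[idx, , drop = FALSE])
      pass <- .ae_pass_cpp(params$layers, params$wy, params$by, Xb, TRUE)
      losses <- c(losses, mean((pass$Y - Xb)^2))
      grads <- list(layers = pass$layers, dwy = pass$dwy, dby = pass$dby)
      up <- adam_update(params, grads, st, cfg$learning_rate)
      params <- up$params; st <- up$state
    }
    history[ep] <- mean(losses)
  }

  model <- structure(list(params = params, cfg = cfg, history = history,
                          n_train = n),
                     class = "lstm_autoencoder")
  model$train_errors <- reconstruction_errors(model, train)
  model
}

#' Reconstruct RF vectors with a fitted autoencoder
#'
#' @param object An `lstm_autoencoder`.
#' @param newdata Numeric matrix (n x 160) of scaled vectors.
#' @param ... Unused.
#' @return Matrix (n x 160) of reconstructions in `[0, 1]`.
#' @export
predict.lstm_autoencoder <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != 160)
    stop("vectors must have length 160", call. = FALSE)
  out <- matrix(0, nrow(newdata), 160L)
  chunk <- 512L
  for (start in seq(1, nrow(newdata), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(newdata))
    Xb <- t(newdata[idx, , drop = FALSE])
    out[idx, ] <- t(.ae_pass_cpp(object$params$layers, object$params$wy,
                                 object$params$by, Xb, FALSE)$Y)
  }
  out
}

#' Per-vector reconstruction errors
#'
#' Mean over the 160 positions of the squared difference between each input
#' vector and its reconstruction.
#'
#' @param model An `lstm_autoencoder`.
#' @param vectors Numeric matrix (n x 160), scaled.
#' @return Numeric vector of n nonnegative errors.
#' @export
reconstruction_errors <- function(model, vectors) {
  vectors <- as.matrix(vectors)
  rec <- predict(model, vectors)
  rowMeans((vectors - rec)^2)
}

#' Reconstruction error of a single RF vector
#'
#' @param model An `lstm_autoencoder`.
#' @param vector Numeric vector of length 160, scaled.
#' @return A single nonnegative error.
#' @export
reconstruction_error <- function(model, vector) {
  if (length(vector) != 160)
    stop("vector must have length 160", call. = FALSE)
  reconstruction_errors(model, matrix(vector, nrow = 1))[1]
}

#' Anomaly threshold from training reconstruction errors
#'
#' The decision threshold is a value exceeding the maximum reconstruction
#' error observed during training: `margin * max(train_errors)` with a
#' multiplicative margin >= 1.
#'
#' @param train_errors Nonempty numeric vector of training errors.
#' @param margin Multiplicative safety margin (>= 1, default 1.05).
#' @return The scalar threshold.
#' @export
#' @examples
#' compute_threshold(c(0.01, 0.02, 0.0625), margin = 1.05)  # 0.065625
compute_threshold <- function(train_errors, margin = 1.05) {
  if (length(train_errors) == 0)
    stop("train_errors must be nonempty", call. = FALSE)
  if (margin < 1) stop("margin must be >= 1", call. = FALSE)
  margin * max(train_errors)
}

#' Classify test vectors as anomalies
#'
#' Scores each test vector by reconstruction error and flags it as an
#' anomaly when the error strictly exceeds the threshold (an error exactly
#' equal to the threshold is not an anomaly). Input order is preserved.
#'
#' @param model An `lstm_autoencoder`.
#' @param threshold Positive decision threshold (see [compute_threshold()]).
#' @param test Numeric matrix (n x 160) of scaled test vectors.
#' @param info Optional tibble with one row per test vector (e.g.
#'   `dataset_split$test_info`); its columns are carried into the result.
#' @return A tibble with columns `source_frame`, `error`, `threshold`,
#'   `is_anomaly` and (if supplied via `info`) `truth_label`.
#' @export
classify <- function(model, threshold, test, info = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  test <- as.matrix(test)
  errors <- reconstruction_errors(model, test)
  res <- tibble::tibble(
    source_frame = if (!is.null(info) && "frame_index" %in% names(info))
      info$frame_index else seq_len(nrow(test)) - 1L,
    error = errors,
    threshold = threshold,
    is_anomaly = errors > threshold,
    truth_label = if (!is.null(info) && "kind" %in% names(info))
      info$kind else NA_character_
  )
  res
}

#' Partition test vectors into anomaly and nonanomaly sets
#'
#' @param results Classification tibble from [classify()], aligned row-for-row
#'   with `test_vectors`.
#' @param test_vectors Numeric matrix (n x 160).
#' @return List with `anomaly` and `nonanomaly` matrices; their row counts
#'   sum to `nrow(test_vectors)`.
#' @export
separate <- function(results, test_vectors) {
  test_vectors <- as.matrix(test_vectors)
  if (nrow(results) != nrow(test_vectors))
    stop("results and test_vectors are misaligned", call. = FALSE)
  flag <- results$is_anomaly
  list(anomaly = test_vectors[flag, , drop = FALSE],
       nonanomaly = test_vectors[!flag, , drop = FALSE])
}

#' @export
print.lstm_autoencoder <- function(x, ...) {
  cat(sprintf("<lstm_autoencoder> encoder %s | decoder %s, %d epochs on %d vectors\n",
              paste(x$cfg$encoder_units, collapse = "/"),
              paste(x$cfg$decoder_units, collapse = "/"),
              x$cfg$epochs, x$n_train))
  cat(sprintf("  final loss %.4g, max train error %.4g\n",
              x$history[length(x$history)], max(x$train_errors)))
  invisible(x)
}

#' @rdname lstm_autoencoder_tidiers
#' @method tidy lstm_autoencoder
#' @export
tidy.lstm_autoencoder <- function(x, ...) {
  tibble::tibble(vector = seq_along(x$train_errors) - 1L,
                 train_error = x$train_errors)
}

#' Tidiers for fitted LSTM autoencoders
#'
#' `tidy()` returns the per-vector training reconstruction errors (the
#' distribution the anomaly threshold is anchored to); `glance()` returns a
#' one-row model summary.
#'
#' @param x An `lstm_autoencoder`.
#' @param ... Unused.
#' @return A tibble.
#' @name lstm_autoencoder_tidiers
#' @method glance lstm_autoencoder
#' @export
glance.lstm_autoencoder <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 epochs = x$cfg$epochs,
                 final_loss = x$history[length(x$history)],
                 max_train_error = max(x$train_errors),
                 mean_train_error = mean(x$train_errors))
}
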