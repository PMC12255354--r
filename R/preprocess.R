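#' Mean frame of a stack
#'
#' Elementwise arithmetic mean over a stack of equally shaped RF frames, the
#' static-background estimate that subtraction removes.
#'
#' @param frames A list of numeric matrices (elements x depth), or an
#'   `rf_dataset` from [simulate_dataset()].
#' @return A numeric matrix, the per-pixel mean.
#' @export
compute_mean_frame <- function(frames) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  check_equal_shapes(frames)
  Reduce(`+`, frames) / length(frames)
}

#' Subtract a background (mean) frame from every frame
#'
#' Coherent background subtraction: `out[[i]] = frames[[i]] - mean_frame`.
#' Static clutter that is constant across the stack cancels exactly; the mean
#' of the outputs is the zero grid up to floating-point error.
#'
#' @param frames A list of numeric matrices or an `rf_dataset`.
#' @param mean_frame Matrix of the same shape (typically from
#'   [compute_mean_frame()]).
#' @return A list of background-subtracted matrices.
#' @export
subtract_background <- function(frames, mean_frame) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  if (!all(dim(frames[[1]]) == dim(mean_frame)))
    stop("mean_frame shape does not match frames", call. = FALSE)
  check_equal_shapes(frames)
  lapply(frames, function(f) f - mean_frame)
}

# Analytic signal of each column of x via the one-sided spectrum construction:
# zero the negative frequencies, double the positive ones, keep DC (and
# Nyquist for even length) unscaled.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Envelope ("B-mode-like") image of an RF frame
#'
#' Per-element magnitude of the analytic signal along the depth axis — the
#' linear (uncompressed) envelope used for thresholding and frame selection.
#'
#' @param frame An `rf_frame`, or a numeric matrix (elements x depth).
#' @return A nonnegative matrix of the same shape.
#' @export
envelope_image <- function(frame) {
  m <- as_frame_matrix(frame)
  # depth runs along rows of t(m); envelope is per element (per column there)
  Mod(t(analytic_signal(t(m))))
}

#' Region-of-interest specification
#'
#' Half-open, 0-based spans of elements and depth samples delimiting the
#' tunnel lumen, plus the center element from which 1-D RF segments are
#' extracted. The depth span must be exactly 160 samples, the autoencoder's
#' input length; the center element is the midpoint of the element span
#' (ties broken toward the lower index).
#'
#' @param element_span Half-open `[e0, e1)` element interval.
#' @param depth_span Half-open `[d0, d1)` depth interval of length 160.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(element_span = c(29L, 34L), depth_span = c(200L, 360L)) {
  element_span <- as.integer(element_span)
  depth_span <- as.integer(depth_span)
  if (length(element_span) != 2 || diff(element_span) < 1 || element_span[1] < 0)
    stop("element_span must be a non-empty half-open interval with e0 >= 0",
         call. = FALSE)
  if (length(depth_span) != 2 || depth_span[1] < 0 || diff(depth_span) != 160L)
    stop("depth_span must be a half-open interval of exactly 160 samples",
         call. = FALSE)
  center <- element_span[1] + (diff(element_span) - 1L) %/% 2L
  structure(list(element_span = element_span, depth_span = depth_span,
                 center_element = center),
            class = "roi_spec")
}

check_roi_bounds <- function(roi, n_elements, n_samples) {
  if (roi$element_span[2] > n_elements || roi$depth_span[2] > n_samples)
    stop("ROI exceeds frame bounds", call. = FALSE)
  invisible(roi)
}

#' Crop an envelope image to a region of interest
#'
#' @param image Numeric matrix (elements x depth).
#' @param roi An [roi_spec()]; spans are 0-based half-open.
#' @return The `element_span` x `depth_span` sub-grid.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  image <- as.matrix(image)
  check_roi_bounds(roi, nrow(image), ncol(image))
  es <- roi$element_span; ds <- roi$depth_span
  image[(es[1] + 1L):es[2], (ds[1] + 1L):ds[2], drop = FALSE]
}

#' Threshold an envelope image
#'
#' Pixels strictly above `level` are kept unchanged; all others are set to 0.
#'
#' @param image Nonnegative numeric matrix.
#' @param level Threshold level, >= 0.
#' @return The thresholded matrix.
#' @export
threshold_image <- function(image, level) {
  if (!is.numeric(level) || length(level) != 1 || level < 0)
    stop("level must be a single nonnegative number", call. = FALSE)
  image <- as.matrix(image)
  image * (image > level)
}

#' Does a thresholded image contain an agent?
#'
#' A frame is kept as an agent-bearing frame when its thresholded envelope
#' retains at least `min_pixels` nonzero pixels; frames with fewer are
#' discarded as empty.
#'
#' @param image A thresholded envelope image.
#' @param min_pixels Minimum count of nonzero pixels (default 3).
#' @return Logical flag.
#' @export
has_uca <- function(image, min_pixels = 3L) {
  if (min_pixels < 1) stop("min_pixels must be >= 1", call. = FALSE)
  sum(as.matrix(image) != 0) >= min_pixels
}

#' Robust envelope noise scale
#'
#' Estimates the Gaussian RF noise standard deviation from pooled envelope
#' pixels. The envelope of white Gaussian noise is Rayleigh distributed, for
#' which the median absolute deviation is 0.44845 x sigma; dividing the MAD
#' by that constant yields a consistent, outlier-insensitive estimate of
#' sigma even when a minority of pixels carry bubble signal.
#'
#' @param values Numeric vector of (subtracted) envelope pixel values.
#' @return Estimated noise sigma.
#' @export
envelope_noise_scale <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no pixel values supplied", call. = FALSE)
  stats::median(abs(values - stats::median(values))) / 0.44845
}

#' Extract the 160-sample center-element RF segment
#'
#' Returns the depth samples of `roi$depth_span` at `roi$center_element`
#' from a (background-subtracted) RF frame, in depth order — the 1-D RF
#' vector the autoencoder consumes.
#'
#' @param frame Numeric matrix (elements x depth) or `rf_frame`.
#' @param roi An [roi_spec()].
#' @return Numeric vector of length 160.
#' @export
extract_center_rf <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  m <- as_frame_matrix(frame)
  check_roi_bounds(roi, nrow(m), ncol(m))
  ds <- roi$depth_span
  m[roi$center_element + 1L, (ds[1] + 1L):ds[2]]
}

# One stack through subtraction -> envelope -> crop -> threshold -> selection
# -> center-element extraction. Envelope detection is per element, so only
# the ROI's element rows are transformed (identical to cropping the full
# envelope image). Returns vectors, per-frame retention log, and the level.
preprocess_stack <- function(frames, roi, level = NULL, min_pixels = 3L,
                             truth = NULL, level_k = 4) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  check_roi_bounds(roi, nrow(frames[[1]]), ncol(frames[[1]]))
  mean_frame <- compute_mean_frame(frames)
  es <- roi$element_span; ds <- roi$depth_span
  rows <- (es[1] + 1L):es[2]

  n <- length(frames)
  env_roi <- vector("list", n)
  center_rf <- matrix(0, n, 160L)
  for (i in seq_len(n)) {
    sub <- frames[[i]] - mean_frame
    env <- Mod(t(analytic_signal(t(sub[rows, , drop = FALSE]))))
    env_roi[[i]] <- env[, (ds[1] + 1L):ds[2], drop = FALSE]
    center_rf[i, ] <- sub[roi$center_element + 1L, (ds[1] + 1L):ds[2]]
  }

  if (is.null(level)) {
    level <- level_k * envelope_noise_scale(unlist(env_roi, use.names = FALSE))
    # floor at the arithmetic precision of the background subtraction, so
    # cancellation dust in noise-free stacks is never mistaken for signal
    level <- max(level, 1e-7 * max(abs(mean_frame)))
  }

  n_pixels <- vapply(env_roi, function(e) sum(e > level), integer(1))
  retained <- n_pixels >= min_pixels
  retention <- tibble::tibble(
    frame_index = vapply(seq_len(n), function(i) i - 1L, integer(1)),
    n_pixels = n_pixels, retained = retained
  )
  if (!is.null(truth)) {
    retention <- dplyr::left_join(retention,
                                  dplyr::select(truth, "frame_index", "kind"),
                                  by = "frame_index")
  } else {
    retention$kind <- NA_character_
  }
  list(vectors = center_rf[retained, , drop = FALSE],
       info = retention[retained, , drop = FALSE],
       retention = retention, level = level, mean_frame = mean_frame)
}

#' Build training and testing RF-vector datasets from two stacks
#'
#' Applies the full frame-selection chain — per-stack mean-frame subtraction,
#' envelope detection, ROI cropping, envelope thresholding, the
#' minimum-nonzero-pixel filter — and extracts the 160-sample center-element
#' RF vector of every retained frame. The normal stack (individual agents
#' only) becomes the training set; the sample stack (which may contain
#' clusters) becomes the testing set. Each stack gets its own mean frame,
#' ROI and threshold level, mirroring a two-tunnel phantom.
#'
#' @param normal_frames,sample_frames Frame stacks (lists of matrices or
#'   `rf_dataset`s). When `rf_dataset`s are given their truth tables are
#'   carried onto the retained vectors.
#' @param roi_normal,roi_sample [roi_spec()]s for the two stacks.
#' @param level Envelope threshold; `NULL` (default) estimates it per stack
#'   as `level_k` times the robust noise scale of the pooled subtracted
#'   envelope over the ROI.
#' @param min_pixels Minimum nonzero pixels for a frame to be retained.
#' @param level_k Multiplier on the robust noise scale when `level` is NULL.
#'
#' @return A `dataset_split`: list with `train`/`test` (n x 160 matrices),
#'   `train_info`/`test_info` (tibbles: frame_index, n_pixels, kind, stack,
#'   group_label), per-stack retention logs and threshold levels.
#' @export
build_datasets <- function(normal_frames, sample_frames,
                           roi_normal = roi_spec(), roi_sample = roi_normal,
                           level = NULL, min_pixels = 3L, level_k = 4) {
  truth_n <- if (inherits(normal_frames, "rf_dataset")) normal_frames$truth
  truth_s <- if (inherits(sample_frames, "rf_dataset")) sample_frames$truth

  pn <- preprocess_stack(normal_frames, roi_normal, level, min_pixels,
                         truth_n, level_k)
  ps <- preprocess_stack(sample_frames, roi_sample, level, min_pixels,
                         truth_s, level_k)
  if (nrow(pn$vectors) == 0)
    stop("empty dataset: no frames retained from the normal stack", call. = FALSE)
  if (nrow(ps$vectors) == 0)
    stop("empty dataset: no frames retained from the sample stack", call. = FALSE)
  if (any(pn$info$kind %in% "cluster"))
    stop("training stack contains cluster events; it must hold individual agents only",
         call. = FALSE)

  pn$info$stack <- "normal"; pn$info$group_label <- "train_normal"
  ps$info$stack <- "sample"; ps$info$group_label <- "test"
  pn$retention$stack <- "normal"; ps$retention$stack <- "sample"

  structure(
    list(train = pn$vectors, train_info = pn$info,
         test = ps$vectors, test_info = ps$info,
         retention = dplyr::bind_rows(pn$retention, ps$retention),
         level_normal = pn$level, level_sample = ps$level,
         min_pixels = as.integer(min_pixels)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d x 160 (levels %.4g), test %d x 160 (level %.4g)\n",
              nrow(x$train), x$level_normal, nrow(x$test), x$level_sample))
  if (!all(is.na(x$test_info$kind)))
    print(dplyr::count(x$test_info, .data$kind))
  invisible(x)
}

# ---- internal frame-container helpers ----

as_frame_list <- function(frames) {
  if (inherits(frames, "rf_dataset")) return(frames$frames)
  if (is.matrix(frames)) return(list(frames))
  stopifnot(is.list(frames))
  frames
}

as_frame_matrix <- function(frame) {
  if (inherits(frame, "rf_frame")) return(frame$samples)
  as.matrix(frame)
}

check_equal_shapes <- function(frames) {
  d1 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) all(dim(f) == d1), logical(1))
  if (!all(ok)) stop("frames differ in shape", call. = FALSE)
  invisible(frames)
}
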