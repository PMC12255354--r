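#' Synthesize one bubble echo waveform
#'
#' A bubble echo is modeled as a Gaussian-windowed sum of a fundamental tone
#' at `f0`, a second harmonic at `2*f0` and a subharmonic at `f0/2`:
#' \deqn{a \, e^{-(t-t_0)^2/2\sigma^2}\left[\sin 2\pi f_0 (t-t_0)
#'   + h_2 \sin 4\pi f_0 (t-t_0) + s \sin \pi f_0 (t-t_0)\right]}
#' with `s = sub_ratio_clu` for cluster events and `sub_ratio_ind`
#' otherwise; cluster events are additionally scaled by `cluster_gain`.
#' This is a phenomenological stand-in for microbubble acoustics: clusters
#' present elevated amplitude and subharmonic energy, not a solution of any
#' bubble-dynamics equation.
#'
#' @param t_axis Uniformly spaced time samples (s) at spacing `1/acq$fs`.
#' @param t0 Event time (s), the center of the pulse envelope.
#' @param amp Peak amplitude (> 0 unless exactly 0, which yields silence).
#' @param echo An [echo_spec()].
#' @param acq An [acquisition_spec()].
#' @param is_cluster Logical; use the cluster subharmonic ratio and gain.
#'
#' @return Numeric waveform, same length as `t_axis`.
#' @export
#' @examples
#' acq <- acquisition_spec()
#' t <- (0:159) / acq$fs
#' w <- bubble_echo(t, t0 = 80 / acq$fs, amp = 1, echo_spec(), acq)
bubble_echo <- function(t_axis, t0, amp, echo, acq, is_cluster = FALSE) {
  stopifnot(inherits(echo, "echo_spec"), inherits(acq, "acquisition_spec"))
  if (amp < 0) stop("amp must be >= 0", call. = FALSE)
  if (length(t_axis) > 1) {
    dt <- diff(t_axis)
    if (max(abs(dt - 1 / acq$fs)) > 1e-9 / acq$fs)
      stop("t_axis must be uniformly spaced at 1/fs", call. = FALSE)
  }
  tau <- t_axis - t0
  s <- if (is_cluster) echo$sub_ratio_clu else echo$sub_ratio_ind
  gain <- if (is_cluster) echo$cluster_gain else 1
  carrier <- sin(2 * pi * acq$f0 * tau) +
    echo$harm2_ratio * sin(2 * pi * 2 * acq$f0 * tau) +
    s * sin(2 * pi * (acq$f0 / 2) * tau)
  amp * gain * exp(-tau^2 / (2 * echo$pulse_sigma^2)) * carrier
}

# Static tunnel-wall clutter: two Gaussian-windowed specular reflection bands
# bracketing the lumen, RF-modulated at f0, with a smooth lateral taper.
# Deterministic in (acq, scene); identical across frames of a run.
clutter_frame <- function(acq, scene) {
  d <- seq_len(acq$n_samples) - 1L
  span <- scene$tunnel_depth_span
  wall_sigma <- 8
  c1 <- span[1] - 30
  c2 <- span[2] - 1 + 30
  depth_profile <- exp(-(d - c1)^2 / (2 * wall_sigma^2)) +
    exp(-(d - c2)^2 / (2 * wall_sigma^2))
  rf <- scene$wall_amplitude * depth_profile * cos(2 * pi * acq$f0 * d / acq$fs)
  e <- seq_len(acq$n_elements) - 1L
  taper <- 0.8 + 0.2 * sin(2 * pi * e / acq$n_elements)
  outer(taper, rf)
}

#' Simulate a single RF frame
#'
#' One frame is the sum of the static tunnel-wall clutter, zero or one bubble
#' event, and i.i.d. Gaussian noise. An event occurs with probability
#' `scene$event_prob` (unless `force_kind` overrides), is a cluster with
#' probability `scene$cluster_frac`, sits at a uniformly random depth within
#' the tunnel lumen on a uniformly random lumen element, and spreads to
#' neighboring elements with Gaussian lateral weight. Randomness is drawn
#' from R's global RNG; seed it (or use [simulate_dataset()]) for
#' reproducibility.
#'
#' @param acq An [acquisition_spec()].
#' @param scene A [scene_spec()].
#' @param echo An [echo_spec()].
#' @param frame_index Integer index recorded in the frame and its truth row.
#' @param force_kind Optional `"empty"`, `"individual"` or `"cluster"` to
#'   override the random event draw.
#' @param clutter Optional precomputed clutter matrix (from one call to the
#'   internal clutter model) so that a stack shares one clutter realization.
#'
#' @return An `rf_frame`: list with `samples` (elements x depth matrix),
#'   `frame_index`, and `truth` (one-row tibble: kind, element, depth, amp).
#' @export
simulate_frame <- function(acq, scene, echo, frame_index = 0L,
                           force_kind = NULL, clutter = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(scene, "scene_spec"),
            inherits(echo, "echo_spec"))
  if (is.null(clutter)) clutter <- clutter_frame(acq, scene)
  samples <- clutter

  kind <- if (!is.null(force_kind)) {
    match.arg(force_kind, c("empty", "individual", "cluster"))
  } else if (stats::runif(1) < scene$event_prob) {
    if (stats::runif(1) < scene$cluster_frac) "cluster" else "individual"
  } else "empty"

  element <- NA_integer_; depth <- NA_real_; amp <- NA_real_
  if (kind != "empty") {
    es <- scene$tunnel_element_span
    element <- es[1] + sample.int(es[2] - es[1], 1L) - 1L
    ds <- scene$tunnel_depth_span
    depth <- stats::runif(1, ds[1], ds[2])
    amp <- exp(stats::rnorm(1, log(echo$amp_mean), echo$amp_sd))
    t_axis <- (seq_len(acq$n_samples) - 1L) / acq$fs
    w <- bubble_echo(t_axis, depth / acq$fs, amp, echo, acq,
                     is_cluster = (kind == "cluster"))
    reach <- ceiling(3 * scene$lateral_sigma)
    rows <- max(0L, element - reach):min(acq$n_elements - 1L, element + reach)
    lat <- exp(-(rows - element)^2 / (2 * scene$lateral_sigma^2))
    samples[rows + 1L, ] <- samples[rows + 1L, ] + outer(lat, w)
  }

  if (scene$noise_sd > 0) {
    samples <- samples +
      matrix(stats::rnorm(length(samples), 0, scene$noise_sd),
             nrow = nrow(samples))
  }

  structure(
    list(samples = samples, frame_index = as.integer(frame_index),
         truth = tibble::tibble(frame_index = as.integer(frame_index),
                                kind = kind, element = element,
                                depth_sample = depth, amp = amp)),
    class = "rf_frame"
  )
}

#' Simulate a labeled RF frame stack
#'
#' Generates `scene$n_frames` frames sharing one clutter realization, with a
#' per-frame ground-truth table. The run is fully determined by the three
#' specs and `scene$seed`.
#'
#' @param acq An [acquisition_spec()].
#' @param scene A [scene_spec()] (its `seed` drives all randomness).
#' @param echo An [echo_spec()].
#'
#' @return An `rf_dataset`: list with `frames` (list of elements x depth
#'   matrices), `truth` (tibble, one row per frame), and the three specs.
#' @export
#' @examples
#' ds <- simulate_dataset(acquisition_spec(n_elements = 8L, n_samples = 256L),
#'                        scene_spec(n_frames = 5, tunnel_depth_span = c(48, 208),
#'                                   tunnel_element_span = c(2, 6)),
#'                        echo_spec())
#' ds$truth
simulate_dataset <- function(acq, scene, echo) {
  stopifnot(inherits(scene, "scene_spec"))
  set.seed(scene$seed)
  clutter <- clutter_frame(acq, scene)
  frames <- vector("list", scene$n_frames)
  truth <- vector("list", scene$n_frames)
  for (i in seq_len(scene$n_frames)) {
    fr <- simulate_frame(acq, scene, echo, frame_index = i - 1L,
                         clutter = clutter)
    frames[[i]] <- fr$samples
    truth[[i]] <- fr$truth
  }
  structure(
    list(frames = frames, truth = dplyr::bind_rows(truth),
         acq = acq, scene = scene, echo = echo),
    class = "rf_dataset"
  )
}

#' @export
print.rf_dataset <- function(x, ...) {
  n_ev <- sum(x$truth$kind != "empty")
  cat(sprintf("<rf_dataset> %d frames (%d x %d), %d events (%d cluster), seed %d\n",
              length(x$frames), x$acq$n_elements, x$acq$n_samples,
              n_ev, sum(x$truth$kind == "cluster"), x$scene$seed))
  invisible(x)
}

#' Write the ground-truth table of a simulated run to CSV
#'
#' @param dataset An `rf_dataset` from [simulate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "rf_dataset"))
  utils::write.csv(dataset$truth, path, row.names = FALSE)
  invisible(path)
}
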