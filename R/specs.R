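#' Acquisition specification
#'
#' Describes the beamformed RF acquisition geometry: sampling rate, transmit
#' (fundamental) frequency, array size and frame depth. The default probe
#' transmits at 2.8 MHz and samples at 4 x f0 = 11.2 MHz, which keeps the
#' second harmonic (5.6 MHz) below Nyquist.
#'
#' @param fs RF sampling rate in Hz. Must satisfy `fs >= 4 * f0` so the
#'   second harmonic is representable.
#' @param f0 Transducer center (fundamental) frequency in Hz.
#' @param n_elements Number of lateral array elements per frame.
#' @param n_samples Depth samples per element per frame (>= 160).
#' @param frame_rate Acquisition frame rate in frames/s (metadata only; the
#'   simulator does not model inter-frame motion).
#'
#' @return An object of class `acquisition_spec`.
#' @export
#' @examples
#' acq <- acquisition_spec()
#' acq$fs / acq$f0   # 4x RF sampling
acquisition_spec <- function(fs = 11.2e6, f0 = 2.8e6, n_elements = 64L,
                             n_samples = 512L, frame_rate = 100) {
  stopifnot(is.numeric(fs), is.numeric(f0), length(fs) == 1, length(f0) == 1)
  if (!(fs > 0 && f0 > 0 && n_elements >= 1 && n_samples > 0 && frame_rate > 0))
    stop("all acquisition parameters must be positive", call. = FALSE)
  if (fs < 2 * (2 * f0))
    stop("fs must be at least 4*f0 so the second harmonic is below Nyquist",
         call. = FALSE)
  if (n_samples < 160)
    stop("n_samples must be >= 160 (the RF segment length)", call. = FALSE)
  structure(
    list(fs = fs, f0 = f0, n_elements = as.integer(n_elements),
         n_samples = as.integer(n_samples), frame_rate = frame_rate),
    class = "acquisition_spec"
  )
}

#' Scene specification
#'
#' Describes one simulated flow-phantom run: how many frames, how often a
#' frame contains a bubble event, what fraction of events are clusters, where
#' the tunnel lumen sits in the frame, and the clutter/noise levels. The
#' defaults emulate a low-concentration protocol in which most frames are
#' empty or carry a single agent, and roughly a quarter of the agents in a
#' cluster sample are clusters.
#'
#' @param n_frames Number of frames to simulate.
#' @param event_prob Probability that a frame contains one bubble event.
#' @param cluster_frac Fraction of events that are cluster (CCMC-like)
#'   events rather than individual microbubbles.
#' @param tunnel_depth_span Half-open 0-based `[d0, d1)` interval of depth
#'   samples spanned by the tunnel lumen; its length must be exactly 160 so
#'   that center-element extraction needs no further windowing.
#' @param tunnel_element_span Half-open 0-based `[e0, e1)` interval of
#'   elements over which events can occur (the lateral extent of the lumen).
#' @param wall_amplitude Peak amplitude of the static tunnel-wall clutter,
#'   in the same arbitrary RF units as the echoes.
#' @param noise_sd Standard deviation of the additive white Gaussian noise.
#' @param lateral_sigma Gaussian spread (in elements) of one echo across
#'   neighboring elements.
#' @param seed Integer seed; a (spec, seed) pair fully determines the run.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_frames = 100L, event_prob = 0.3, cluster_frac = 0.25,
                       tunnel_depth_span = c(200L, 360L),
                       tunnel_element_span = c(29L, 34L),
                       wall_amplitude = 1, noise_sd = 0.02,
                       lateral_sigma = 3, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (event_prob < 0 || event_prob > 1)
    stop("event_prob must lie in [0, 1]", call. = FALSE)
  if (cluster_frac < 0 || cluster_frac > 1)
    stop("cluster_frac must lie in [0, 1]", call. = FALSE)
  tunnel_depth_span <- as.integer(tunnel_depth_span)
  tunnel_element_span <- as.integer(tunnel_element_span)
  if (length(tunnel_depth_span) != 2 ||
      diff(tunnel_depth_span) != 160L || tunnel_depth_span[1] < 0)
    stop("tunnel_depth_span must be a half-open interval of exactly 160 depth samples",
         call. = FALSE)
  if (length(tunnel_element_span) != 2 ||
      diff(tunnel_element_span) < 1L || tunnel_element_span[1] < 0)
    stop("tunnel_element_span must be a non-empty half-open interval", call. = FALSE)
  if (wall_amplitude < 0 || noise_sd < 0 || lateral_sigma <= 0)
    stop("wall_amplitude, noise_sd must be >= 0 and lateral_sigma > 0", call. = FALSE)
  structure(
    list(n_frames = as.integer(n_frames), event_prob = event_prob,
         cluster_frac = cluster_frac,
         tunnel_depth_span = tunnel_depth_span,
         tunnel_element_span = tunnel_element_span,
         wall_amplitude = wall_amplitude, noise_sd = noise_sd,
         lateral_sigma = lateral_sigma, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Echo specification
#'
#' Parameters of the simulated bubble echoes. An individual microbubble echo
#' is a Gaussian-windowed tone burst at the fundamental with weak second
#' harmonic and subharmonic components; a cluster echo carries a
#' multiplicative amplitude gain and a substantially stronger subharmonic
#' component, the two signatures that set cluster acoustics apart.
#'
#' @param amp_mean,amp_sd Log-normal parameters of the individual-bubble peak
#'   amplitude: `amp ~ exp(Normal(log(amp_mean), amp_sd))`, arbitrary RF units.
#' @param cluster_gain Multiplicative amplitude factor (> 1) applied to
#'   cluster events.
#' @param sub_ratio_ind,sub_ratio_clu Subharmonic-to-fundamental component
#'   ratio for individual and cluster echoes; clusters must exceed individuals.
#' @param harm2_ratio Second-harmonic component ratio (both populations).
#' @param pulse_sigma Width (standard deviation, seconds) of the Gaussian
#'   pulse envelope.
#'
#' @return An object of class `echo_spec`.
#' @export
echo_spec <- function(amp_mean = 1, amp_sd = 0.1, cluster_gain = 3,
                      sub_ratio_ind = 0.05, sub_ratio_clu = 0.4,
                      harm2_ratio = 0.2, pulse_sigma = 1e-6) {
  if (amp_mean <= 0 || amp_sd < 0)
    stop("amp_mean must be > 0 and amp_sd >= 0", call. = FALSE)
  if (cluster_gain <= 1) stop("cluster_gain must exceed 1", call. = FALSE)
  if (!(sub_ratio_clu > sub_ratio_ind && sub_ratio_ind >= 0))
    stop("require sub_ratio_clu > sub_ratio_ind >= 0", call. = FALSE)
  if (harm2_ratio < 0) stop("harm2_ratio must be >= 0", call. = FALSE)
  if (pulse_sigma <= 0) stop("pulse_sigma must be > 0", call. = FALSE)
  structure(
    list(amp_mean = amp_mean, amp_sd = amp_sd, cluster_gain = cluster_gain,
         sub_ratio_ind = sub_ratio_ind, sub_ratio_clu = sub_ratio_clu,
         harm2_ratio = harm2_ratio, pulse_sigma = pulse_sigma),
    class = "echo_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> fs=%.3g Hz, f0=%.3g Hz, %d elements x %d samples, %.5g fps\n",
              x$fs, x$f0, x$n_elements, x$n_samples, x$frame_rate))
  invisible(x)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d frames, P(event)=%.3g, P(cluster|event)=%.3g, depth [%d,%d), elements [%d,%d), seed=%d\n",
              x$n_frames, x$event_prob, x$cluster_frac,
              x$tunnel_depth_span[1], x$tunnel_depth_span[2],
              x$tunnel_element_span[1], x$tunnel_element_span[2], x$seed))
  invisible(x)
}

#' @export
print.echo_spec <- function(x, ...) {
  cat(sprintf("<echo_spec> amp~LogN(log(%.3g),%.3g), cluster gain %.3g, sub ratios %.3g/%.3g, h2 %.3g\n",
              x$amp_mean, x$amp_sd, x$cluster_gain,
              x$sub_ratio_ind, x$sub_ratio_clu, x$harm2_ratio))
  invisible(x)
}
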