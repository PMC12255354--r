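#' Frequency band specification
#'
#' A symmetric band `center +/- half_width` (Hz) over which a band amplitude
#' is summarized. Defaults for the fundamental and subharmonic bands are
#' provided by [fundamental_band()] and [subharmonic_band()].
#'
#' @param center Band center, Hz; must exceed `half_width` so the band stays
#'   above DC.
#' @param half_width Band half width, Hz.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center, half_width) {
  if (center - half_width <= 0)
    stop("band must lie strictly above DC (center - half_width > 0)",
         call. = FALSE)
  if (half_width < 0) stop("half_width must be >= 0", call. = FALSE)
  structure(list(center = center, half_width = half_width),
            class = "band_spec")
}

#' @rdname band_spec
#' @param acq An [acquisition_spec()]; the fundamental band is centered on
#'   `f0` and the subharmonic band on `f0/2`, each with half width
#'   `frac * f0`.
#' @param frac Fractional half width relative to `f0` (default 0.15).
#' @export
fundamental_band <- function(acq, frac = 0.15) {
  band_spec(acq$f0, frac * acq$f0)
}

#' @rdname band_spec
#' @export
subharmonic_band <- function(acq, frac = 0.15) {
  band_spec(acq$f0 / 2, frac * acq$f0)
}

#' One-sided DFT magnitude spectrum of a 160-sample RF vector
#'
#' Rectangular (unwindowed) DFT of the raw RF segment; bins are
#' `k * fs / 160` for `k = 0..80`. Spectra are computed on unnormalized RF
#' amplitudes so that band amplitudes retain their physical ordering.
#'
#' @param vector Numeric RF vector of length 160.
#' @param fs Sampling rate, Hz.
#' @return A tibble with columns `freq` (Hz) and `magnitude` (81 rows).
#' @export
magnitude_spectrum <- function(vector, fs) {
  if (length(vector) != 160)
    stop("vector must have length 160", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  X <- stats::fft(vector)
  k <- 0:80
  tibble::tibble(freq = k * fs / 160, magnitude = Mod(X)[k + 1])
}

# magnitudes for a whole matrix of vectors at once (rows = vectors)
magnitude_spectra <- function(vectors, fs) {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 160)
  Mod(stats::mvfft(t(vectors)))[1:81, , drop = FALSE]
}

band_bins <- function(freqs, band) {
  sel <- abs(freqs - band$center) <= band$half_width
  if (!any(sel))
    stop("band contains no DFT bin at this fs and segment length", call. = FALSE)
  sel
}

#' Mean spectral magnitude over a frequency band
#'
#' @param freqs Bin frequencies, Hz.
#' @param magnitude Nonnegative magnitudes, same length.
#' @param band A [band_spec()].
#' @param stat Band statistic, `"mean"` (default) or `"max"` over the
#'   selected bins.
#' @return The band amplitude.
#' @export
band_amplitude <- function(freqs, magnitude, band, stat = c("mean", "max")) {
  stopifnot(inherits(band, "band_spec"), length(freqs) == length(magnitude))
  stat <- match.arg(stat)
  sel <- band_bins(freqs, band)
  if (stat == "mean") mean(magnitude[sel]) else max(magnitude[sel])
}

#' Mean spectrum of a group of RF vectors
#'
#' Bin-wise mean of the member magnitude spectra, with fundamental and
#' subharmonic band amplitudes evaluated on the mean spectrum and the
#' trapezoidal area under the mean spectrum.
#'
#' @param vectors Numeric matrix (n x 160) of raw RF vectors.
#' @param fs Sampling rate, Hz.
#' @param fund_band,sub_band [band_spec()]s for the fundamental and
#'   subharmonic regions.
#' @param stat Band statistic passed to [band_amplitude()].
#' @return A list of class `group_spectrum`: `spectrum` tibble
#'   (freq, magnitude), `fund_amp`, `sub_amp`, `auc`, `n`.
#' @export
group_mean_spectrum <- function(vectors, fs, fund_band, sub_band,
                                stat = "mean") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0) stop("empty group", call. = FALSE)
  mags <- magnitude_spectra(vectors, fs)
  m <- rowMeans(mags)
  freqs <- (0:80) * fs / 160
  structure(
    list(spectrum = tibble::tibble(freq = freqs, magnitude = m),
         fund_amp = band_amplitude(freqs, m, fund_band, stat),
         sub_amp = band_amplitude(freqs, m, sub_band, stat),
         auc = pracma::trapz(freqs, m),
         n = nrow(vectors)),
    class = "group_spectrum"
  )
}

#' Per-vector subharmonic-vs-fundamental scatter points
#'
#' One point per RF vector: `fund_amp` is the band amplitude in the
#' fundamental region and `sub_amp` in the subharmonic region, both from the
#' vector's own magnitude spectrum.
#'
#' @param groups Named list of numeric matrices (n_g x 160), raw RF units.
#' @param fs Sampling rate, Hz.
#' @param fund_band,sub_band [band_spec()]s.
#' @param stat Band statistic passed to [band_amplitude()].
#' @return A tibble with columns `group`, `fund_amp`, `sub_amp`.
#' @export
scatter_points <- function(groups, fs, fund_band, sub_band, stat = "mean") {
  stopifnot(is.list(groups), !is.null(names(groups)))
  freqs <- (0:80) * fs / 160
  fsel <- band_bins(freqs, fund_band)
  ssel <- band_bins(freqs, sub_band)
  purrr::imap_dfr(groups, function(v, nm) {
    v <- as.matrix(v)
    if (nrow(v) == 0) return(tibble::tibble())
    mags <- magnitude_spectra(v, fs)
    if (stat == "mean") {
      fa <- colMeans(mags[fsel, , drop = FALSE])
      sa <- colMeans(mags[ssel, , drop = FALSE])
    } else {
      fa <- apply(mags[fsel, , drop = FALSE], 2, max)
      sa <- apply(mags[ssel, , drop = FALSE], 2, max)
    }
    tibble::tibble(group = nm, fund_amp = fa, sub_amp = sa)
  })
}

#' Ordinary least-squares fit of subharmonic on fundamental amplitude
#'
#' Fits `sub_amp = intercept + slope * fund_amp` by OLS (via [stats::lm()])
#' and reports the coefficient of determination.
#'
#' @param points A data frame with columns `fund_amp` and `sub_amp` (or `x`
#'   and `y`).
#' @return A tibble with columns `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(points) {
  points <- as.data.frame(points)
  if (all(c("x", "y") %in% names(points)))
    names(points)[match(c("x", "y"), names(points))] <- c("fund_amp", "sub_amp")
  x <- points$fund_amp; y <- points$sub_amp
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("linear fit needs >= 2 points with distinct x values", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  co <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  tibble::tibble(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n = length(x))
}

#' Frequency-domain comparison of detection groups
#'
#' Computes per-group mean spectra, band amplitudes, area under the mean
#' spectrum, per-vector scatter points and their OLS fits, and orders the
#' scatter slopes. The groups must include `train`, `test_anomaly` and
#' `test_nonanomaly`; additional groups (e.g. `control`) are carried through.
#'
#' @param groups Named list of numeric matrices (raw RF units).
#' @param fs Sampling rate, Hz.
#' @param fund_band,sub_band [band_spec()]s; default bands require an `acq`.
#' @param acq Optional [acquisition_spec()] used to derive default bands.
#' @param stat Band statistic, `"mean"` or `"max"`.
#' @return A `spectral_report`: list with `summary` (tibble: group, n,
#'   fund_amp, sub_amp, auc, slope, intercept, r_squared), `spectra` (long
#'   tibble of mean spectra), `points` (scatter tibble), and
#'   `slope_ordering` (logical: anomaly slope exceeds every other group's).
#' @export
compare_groups <- function(groups, fs, fund_band = NULL, sub_band = NULL,
                           acq = NULL, stat = "mean") {
  required <- c("train", "test_anomaly", "test_nonanomaly")
  if (!all(required %in% names(groups)))
    stop("groups must include: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (is.null(fund_band) || is.null(sub_band)) {
    if (is.null(acq))
      stop("supply fund_band and sub_band, or an acq to derive them",
           call. = FALSE)
    fund_band <- fund_band %||% fundamental_band(acq)
    sub_band <- sub_band %||% subharmonic_band(acq)
  }
  gspec <- purrr::map(groups, group_mean_spectrum, fs = fs,
                      fund_band = fund_band, sub_band = sub_band, stat = stat)
  pts <- scatter_points(groups, fs, fund_band, sub_band, stat)
  fits <- pts |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ linear_fit(.x)) |>
    dplyr::ungroup()
  summary <- purrr::imap_dfr(gspec, function(g, nm) {
    tibble::tibble(group = nm, n = g$n, fund_amp = g$fund_amp,
                   sub_amp = g$sub_amp, auc = g$auc)
  }) |>
    dplyr::left_join(dplyr::select(fits, -"n"), by = "group")
  spectra <- purrr::imap_dfr(gspec, function(g, nm) {
    dplyr::mutate(g$spectrum, group = nm)
  })
  an_slope <- fits$slope[fits$group == "test_anomaly"]
  slope_ordering <- all(an_slope > fits$slope[fits$group != "test_anomaly"])
  structure(
    list(summary = summary, spectra = spectra, points = pts,
         fund_band = fund_band, sub_band = sub_band, fs = fs,
         slope_ordering = slope_ordering),
    class = "spectral_report"
  )
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("<spectral_report>\n")
  print(x$summary)
  cat(sprintf("anomaly slope exceeds all other groups: %s\n",
              x$slope_ordering))
  invisible(x)
}
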