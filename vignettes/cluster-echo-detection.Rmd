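---
title: "Detecting microbubble-cluster acoustics with an LSTM autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microbubble-cluster acoustics with an LSTM autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ultrasound contrast agents (UCAs) are lipid-shelled gas microbubbles that
scatter ultrasound strongly and nonlinearly. Chemically crosslinked
microbubble clusters (CCMCs) — several microbubbles bound into one larger
agent — are expected to produce echoes with **higher amplitude** and
**elevated fundamental and subharmonic energy** than individual bubbles.
`clusterecho` implements a pipeline that finds such cluster echoes in
beamformed radio-frequency (RF) frame stacks without any labeled cluster
examples: an LSTM autoencoder is trained exclusively on echoes of individual
microbubbles, and test echoes whose reconstruction error exceeds the largest
error seen during training are flagged as anomalies. The flagged and
unflagged echoes are then compared in the frequency domain.

Because no public RF data of this kind exist, the package ships a
**synthetic flow-phantom simulator** that generates labeled frame stacks
with known cluster content. Everything downstream — preprocessing, detector,
spectral analysis — is agnostic to whether the frames are simulated or real.

## The simulator

One RF frame is an `n_elements x n_samples` real matrix:

* **Static clutter** — two Gaussian-windowed specular reflection bands
  ("tunnel walls") bracketing the lumen, RF-modulated at the transmit
  frequency, with a smooth lateral taper. Deterministic and identical across
  the frames of a run, so coherent mean-frame subtraction removes it
  exactly.
* **At most one bubble event per frame** with probability `event_prob`,
  mirroring a low-concentration protocol designed to isolate single-agent
  echoes. An event is a Gaussian-windowed tone burst

  $$a\,e^{-(t-t_0)^2/2\sigma^2}\Big[\sin 2\pi f_0 (t-t_0)
    + h_2 \sin 4\pi f_0 (t-t_0) + s \sin \pi f_0 (t-t_0)\Big],$$

  with peak amplitude $a$ log-normal, placed at a uniform depth inside the
  lumen and on a uniform lumen element, spreading to neighboring elements
  with Gaussian lateral weight. Cluster events get a multiplicative gain
  (`cluster_gain`, default 3) and a much larger subharmonic ratio
  ($s = 0.4$ vs $0.05$) — the two signatures that make cluster acoustics
  distinctive. This is a phenomenological echo model: it reproduces the
  *spectral geometry* of the problem, not bubble dynamics (no
  Rayleigh–Plesset physics, no coalescence mechanics, no inter-frame flow).
* **White Gaussian noise** (`noise_sd`, default 2% of the mean echo
  amplitude).

Default acquisition: $f_0 = 2.8$ MHz, $f_s = 4 f_0 = 11.2$ MHz, 64 elements,
512 depth samples. The transmit and sampling frequencies of the motivating
experiments are not published; $4 f_0$ sampling is a common RF convention
and keeps the second harmonic below Nyquist. The lumen spans exactly 160
depth samples so that the extracted center-element segment needs no further
windowing. A quarter of the events in a cluster-bearing suspension are
clusters (`cluster_frac = 0.25`).

The lateral geometry deserves a note: echoes are extracted from the *center
element* of the lumen, so the simulator confines events to a narrow
five-element lumen (`tunnel_element_span`) with a lateral spread of three
elements. A lumen much wider than the lateral point-spread would make the
center-element convention discard most event energy — physically, the
tunnel diameter is small compared with the aperture.

**What passing tests on this simulator do and do not show.** They show the
pipeline is correct (each step matches independent oracles), well calibrated
(no anomalies on cluster-free data), and able to separate populations whose
amplitude and subharmonic content differ the way cluster echoes are expected
to differ. They do not show that real CCMC echoes are separable — real
microbubble spectra include shell resonance, size dispersion, and
depth-dependent attenuation this generator does not emulate.

## Preprocessing (frame selection)

Five steps per stack, each its own tested function:

1. **Mean-frame subtraction** (`compute_mean_frame()`,
   `subtract_background()`): the stack mean is subtracted from every frame.
   Subtraction happens on the *RF* (coherent) data, before envelope
   formation, because coherent subtraction cancels static clutter exactly;
   applying it to envelope images would leave a speckle-like residue.
2. **Envelope formation** (`envelope_image()`): per-element magnitude of the
   analytic signal along depth, computed by the one-sided-spectrum FFT
   construction. The linear envelope is used directly — log compression
   would introduce a dynamic-range parameter with no principled default.
3. **ROI cropping** (`crop_roi()`): 0-based, half-open element/depth spans;
   the depth span is exactly 160 samples. The ROI is supplied in
   configuration (on real data it would be chosen manually).
4. **Thresholding and selection** (`threshold_image()`, `has_uca()`):
   envelope pixels at or below `level` are zeroed; a frame is retained when
   at least 3 pixels survive. `level` defaults to $4\hat\sigma$ where
   $\hat\sigma$ is a robust estimate of the RF noise standard deviation from
   the pooled subtracted-envelope pixels. Since the envelope of Gaussian
   noise is Rayleigh distributed, the estimator divides the median absolute
   deviation by 0.44845 (the Rayleigh MAD constant) rather than using the
   Gaussian constant 1.4826 — with the Gaussian constant the level would sit
   near $2.7\sigma$ and empty frames would be retained at tens of percent;
   at $4\sigma$ the empty-frame retention rate is about 0.3%. The level is
   floored at $10^{-7}$ of the background magnitude so that, in noise-free
   degenerate stacks, floating-point cancellation dust left by the mean
   subtraction is never mistaken for signal.
5. **Center-element extraction** (`extract_center_rf()`): the 160 depth
   samples at the ROI's center element, the unit the detector consumes.

`build_datasets()` runs both stacks — each with its own mean frame, ROI and
level, mirroring a two-tunnel phantom — and emits the training set (normal
stack, individual agents only) and the testing set (sample stack).

## The detector

Amplitudes are min–max scaled to $[0,1]$ with bounds fitted on the
*training set only*; test values are clipped after scaling, so out-of-range
(high-amplitude) test echoes saturate. The autoencoder is a symmetric stack
of six LSTM layers — encoder widths 32/16/8, decoder 8/16/32 — on the
160-step sequence (one feature per step), with the encoder's final hidden
state repeated across time as the decoder input and a time-distributed
single-unit sigmoid output. Training minimizes MSE with Adam
(learning rate $10^{-3}$, batch 128, 30 epochs, fixed seed).

Numerical choices: weights use Glorot-uniform initialization with the
forget-gate bias at 1; the training/scoring pass runs in single precision
with fused gate kernels (compiled code), the convention of deep-learning
frameworks, while the optimizer accumulates in double; a double-precision
pure-R reference implementation of the same network is kept in the package
and the test suite verifies the two agree and that the analytic gradients
match finite differences. Widths of 32/16/8 (rather than a 128-wide stack)
and 30 epochs were chosen because training loss on simulated echoes
plateaus within a few epochs and the wider stack multiplies CPU cost
roughly tenfold without changing the decision boundary; the architecture
width and epoch count are exposed in `model_config()`.

The decision rule is deliberately simple and auditable:

* threshold $=$ `margin` $\times$ max training reconstruction error, with
  `margin = 1.05`. A multiplicative margin is recorded, reproducible, and
  scale-free; "exceeding the maximum" alone does not pin down a number.
* a test vector is an anomaly iff its error **strictly** exceeds the
  threshold, so an error exactly at the threshold is not an anomaly.

## Spectral comparison

Spectra are computed on the *unnormalized* RF vectors (rectangular window,
one-sided 81-bin DFT) so amplitudes keep their physical ordering. Band
amplitudes are the mean magnitude over the fundamental band
($f_0 \pm 0.15 f_0$) and subharmonic band ($f_0/2 \pm 0.15 f_0$); the band
statistic can be switched to `max`. `compare_groups()` reports per-group
mean spectra, band amplitudes, trapezoidal area under the mean spectrum,
per-vector subharmonic-vs-fundamental scatter, and OLS fits — the expected
picture being a markedly larger slope and band energy for the detected
anomalies.

## End-to-end runs and calibration

`run_experiment()` composes the whole chain; `run_control()` repeats it
with clusters removed from both stacks, where a calibrated detector should
flag (essentially) nothing. Because the simulator is stochastic, the
control expectation is stated as an anomaly rate $\le 1\%$ rather than an
absolute zero. Because the training-error maximum sits in a smooth tail of
the error distribution (errors track per-echo energy, whose spread comes
from the log-normal amplitudes and the lateral position mixture), a control
run over ~500 test vectors occasionally produces a single false positive at
the default margin; the observed control rates stay in the low per-mille
range. A
single top-level seed derives per-stage seeds by stage-name hashing, so a
run is bitwise reproducible (given unchanged BLAS/threading) and stages can
be rerun in isolation. Artifacts (vector matrices, retention log, results,
spectra, report) are written as CSV/JSON, and `recount_run()` reproduces
the report counts from the persisted files.

The packaged study scale — used by the test suite and
`scripts/acceptance.R` — simulates 6,900 normal-stack and 1,725
sample-stack frames per run, retaining roughly 2,000 training and 500
testing vectors at the default 0.3 event probability. Degenerate inputs are
defined errors: empty stacks, a training stack containing cluster truth,
constant training data (degenerate normalization), fewer than two distinct
abscissae in a fit.

## Known limitations

* The echo model is phenomenological; none of the resonance physics that
  produces real subharmonics is simulated, and attenuation, speckle from
  diffuse scatterers, and inter-frame bubble motion are absent.
* The detector's threshold is anchored to the training *maximum*, which is
  sensitive to training-set outliers; on real data a quantile-based rule
  may be preferable (not implemented, to keep the decision rule the audited
  one).
* Single precision in the compiled pass means reproducibility is exact for
  a fixed build and BLAS but not across numerics libraries.
* With one event per frame and a single scatterer per event, the retained
  frame count scales directly with `event_prob`; overlapping events are out
  of scope.
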