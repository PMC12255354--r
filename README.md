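# clusterecho

Acoustic detection of microbubble-cluster signatures in contrast-enhanced
ultrasound RF data.

## What it does, and for whom

Lipid-shelled microbubbles (ultrasound contrast agents, UCAs) scatter
ultrasound strongly; chemically crosslinked microbubble clusters (CCMCs)
are expected to return echoes with **higher amplitude** and **elevated
fundamental and subharmonic energy** than individual bubbles. For
researchers working on contrast agents, flow phantoms, and ultrasound
localization microscopy, `clusterecho` provides a tested, reusable pipeline
that flags such cluster echoes in beamformed RF frame stacks **without any
labeled cluster examples**:

1. **Simulate** (`simulate_dataset()`) — a labeled synthetic flow-phantom
   generator: static tunnel-wall clutter, sparse single-bubble events,
   cluster events with amplitude gain and strong subharmonic content,
   additive noise. It stands in for proprietary phantom recordings and
   provides ground truth for every frame.
2. **Preprocess** (`build_datasets()`) — mean-frame (background)
   subtraction on the coherent RF, analytic-signal envelope, ROI crop,
   envelope thresholding, a ≥ 3-nonzero-pixel frame filter, and extraction
   of the 160-sample RF segment at the ROI's center element.
3. **Detect** (`train_autoencoder()`, `classify()`) — an LSTM autoencoder
   (encoder 32/16/8, mirrored decoder, sigmoid output) trained only on
   individual-bubble vectors scaled to [0, 1]. With reconstruction error
   $e(x) = \frac{1}{160}\lVert x - \hat x\rVert^2$ and training errors
   $e_1,\dots,e_n$, the decision rule is

   $$\text{anomaly}(x) \iff e(x) > 1.05 \cdot \max_i e_i .$$

4. **Compare** (`compare_groups()`) — one-sided DFT magnitude spectra of
   the raw RF vectors; mean magnitude in the fundamental ($f_0 \pm 0.15
   f_0$) and subharmonic ($f_0/2 \pm 0.15 f_0$) bands; per-vector
   subharmonic-vs-fundamental scatter with OLS fits per group.

`run_experiment()` / `run_control()` orchestrate everything from one
seeded `run_config()`; the control run (no clusters anywhere) is the
calibration check — a sound detector flags essentially nothing.

## Worked example

```r
library(clusterecho)

cfg <- run_config(mode = "experiment",
                  n_train_frames = 600L, n_test_frames = 300L,
                  model = model_config(epochs = 10L), seed = 11L)
run <- run_experiment(cfg)
print(run$report)
#> <run_report> mode=experiment seed=11
#>   frames 900 simulated, 301 retained (196 train / 105 test)
#>   threshold 0.01448 (margin 1.05 over max train error 0.01379)
#>   anomalies 27 / 105 (rate 0.257)
#>   sensitivity (cluster) 1.000
#>   specificity (individual) 0.987
```

Of 900 simulated frames, 301 contained a bubble event and survived frame
selection; 196 individual-bubble vectors trained the autoencoder. The
threshold is 1.05 times the worst training reconstruction error. 27 of the
105 test vectors exceeded it — every true cluster (sensitivity 1.000) and
almost no individual bubbles (specificity 0.987); the anomaly rate (0.257)
tracks the simulated cluster fraction (0.25). The spectral comparison shows
why the detector separates them:

```r
run$spectral$summary
#> # A tibble: 3 × 8
#>   group               n fund_amp sub_amp       auc  slope intercept r_squared
#>   <chr>           <int>    <dbl>   <dbl>     <dbl>  <dbl>     <dbl>     <dbl>
#> 1 train             196     5.55   0.438  7109744. 0.0485     0.169    0.0799
#> 2 test_anomaly       27    16.2    6.46  24151441. 0.512     -1.85     0.890
#> 3 test_nonanomaly    78     5.45   0.427  7074175. 0.0328     0.248    0.0618
```

The detected anomalies carry roughly 3x the fundamental-band amplitude,
15x the subharmonic-band amplitude, and a far steeper
subharmonic-vs-fundamental slope than the nonanomalous test echoes — the
cluster acoustic signature. `autoplot(run$spectral, "spectra")`,
`autoplot(run$spectral, "scatter")` and
`plot_error_distribution(run$results, run$model$train_errors)` draw the
corresponding figures, and `tidy()` / `glance()` summarize the fitted
model.

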