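# Shared fixtures: a small acquisition for fast unit tests, the full-scale
# configuration used by the acceptance properties, and a memoised run cache
# so expensive pipeline runs are computed once per test session.

tiny_acq <- function() {
  acquisition_spec(n_elements = 8L, n_samples = 256L)
}

tiny_scene <- function(...) {
  scene_spec(tunnel_depth_span = c(48L, 208L), tunnel_element_span = c(2L, 6L),
             ...)
}

tiny_roi <- function() {
  roi_spec(element_span = c(2L, 6L), depth_span = c(48L, 208L))
}

tiny_model <- function(epochs = 3L, ...) {
  model_config(encoder_units = c(8L, 4L, 2L), batch_size = 32L,
               epochs = epochs, ...)
}

# Study-condition scale: ~2000 retained training vectors and ~500 retained
# test vectors at the default 0.3 event probability and retention near 1
# for event frames.
acceptance_config <- function(mode, seed) {
  run_config(mode = mode, n_train_frames = 6900L, n_test_frames = 1725L,
             seed = as.integer(seed))
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

acc_control_run <- function(seed) {
  cached_run(paste0("control_", seed),
             run_control(acceptance_config("control", seed)))
}

acc_experiment_run <- function(seed) {
  cached_run(paste0("experiment_", seed),
             run_experiment(acceptance_config("experiment", seed)))
}
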