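# Shared fixtures, built in code at test time.

# A flattened image assembled directly from a density matrix, for extraction
# unit tests (x_axis in radians starting at 0, y_axis in pixels).
make_flat <- function(density, y_axis = seq_len(ncol(density)) - 1,
                      x_pitch = 0.01, b = 1, theta_r = 0) {
  spiraltrace:::flattened_image(
    density,
    x_axis = (seq_len(nrow(density)) - 1) * x_pitch,
    y_axis = y_axis,
    params = spiral_params(b, theta_r), alpha = 1, beta = 1)
}

# A profile assembled directly, for resampling unit tests.
make_profile <- function(phi, y, b = 1, theta_r = 0, beta = 1) {
  structure(list(phi = phi, y = y, n_original_pixels = sum(!is.na(y)),
                 params = spiral_params(b, theta_r), beta = beta,
                 s = NULL, cropping_ratio = NA_real_),
            class = "spiral_profile")
}

# Small, fast simulation spec for pipeline-level tests.
quick_spec <- function(...) {
  simulation_spec(image_size = 480L, turns = 3, ...)
}

run_quick_pipeline <- function(spec) {
  spiraltrace:::pipeline_on_sample(simulate_drawing(spec))
}

# Pre-normalization deviation values in source pixels.
signal_px <- function(sig) {
  sig$y * sig$rms_raw / sqrt(mean(sig$y^2))
}
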