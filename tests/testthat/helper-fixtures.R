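# shared fixture builders: everything is generated in code, no stored data

tiny_params <- function(noise_sigma = 0, ...) {
  acquisition_params(frame_rate = 70, exposure = 1.4, pixel_pitch = 5,
                     fov_diameter = 320, lateral_resolution = 10,
                     noise_sigma = noise_sigma, ...)
}

# constant-intensity frame
flat_frame <- function(value = 0.5, n = 32, params = tiny_params(),
                       gamma_encoded = FALSE) {
  new_frame(matrix(value, n, n), params, gamma_encoded = gamma_encoded)
}

# bright disk of radius r centered at (cx, cy) (0-based) on dark background
disk_frame <- function(n = 128, cx = 64, cy = 64, r = 50,
                       fg = 0.8, bg = 0.02, params = tiny_params()) {
  idx <- seq_len(n) - 1
  x <- matrix(idx, n, n, byrow = TRUE)
  y <- matrix(idx, n, n)
  px <- matrix(bg, n, n)
  px[(x - cx)^2 + (y - cy)^2 <= r^2] <- fg
  new_frame(px, params)
}

# static noise-free sequence of k identical-scene frames
static_sequence <- function(k = 5, n = 32, seed = 2, density = 400,
                            params = tiny_params()) {
  ph <- generate_phantom(c(600, 600), density, seed = seed)
  render_sequence(ph, trajectory_spec(0), params, k, seed = seed,
                  size_px = n, apply_mask = FALSE, apply_honeycomb = FALSE)
}

# Gaussian feature set for divergence tests
gaussian_feature_set <- function(n, mu, sigma = 1, d = 4, label = "g",
                                 seed = 1) {
  set.seed(seed)
  feature_set(matrix(stats::rnorm(n * d, mu, sigma), n, d), label)
}
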