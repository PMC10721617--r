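test_that("gamma linearization and encoding are exact inverses", {
  f <- flat_frame(0.25, gamma_encoded = TRUE)
  expect_equal(linearize(f, 1)$pixels, f$pixels)
  # 0.25^(1/0.5) = 0.0625 ; 0.25^0.5 = 0.5
  expect_equal(linearize(f, 0.5)$pixels[1, 1], 0.0625)
  g <- flat_frame(0.25, gamma_encoded = FALSE)
  expect_equal(encode_gamma(g, 0.5)$pixels[1, 1], 0.5)

  set.seed(4)
  px <- matrix(runif(64), 8, 8)
  fr <- new_frame(px, tiny_params(), gamma_encoded = TRUE)
  round_trip <- encode_gamma(linearize(fr, 0.7), 0.7)
  expect_equal(round_trip$pixels, px, tolerance = 1 / 65535)
  expect_true(round_trip$gamma_encoded)

  # monotone for any gamma > 0
  ord <- order(px)
  expect_equal(order(encode_gamma(new_frame(px, tiny_params()), 2.2)$pixels),
               ord)
  expect_error(linearize(flat_frame(0.5), 0.5), "not gamma encoded")
  expect_error(linearize(flat_frame(0.5, gamma_encoded = TRUE), -1), "positive")
})

test_that("frame averaging computes the mean and the equivalent acquisition", {
  p <- hf_hrme_params()
  frames <- lapply(0:4, function(i) {
    new_frame(matrix(i / 4, 8, 8), p, timestamp = i * 1000 / 70)
  })
  s <- new_sequence(frames, selected_index = 5)
  avg <- average_frames(s, 5)
  # mean of (0, .25, .5, .75, 1) = 0.5
  expect_equal(avg$frame$pixels, matrix(0.5, 8, 8))
  expect_equal(avg$equivalent_frame_rate, 14)   # 70 fps / 5
  expect_equal(avg$composite_exposure, 7)       # 5 x 1.4 ms
  expect_error(average_frames(s, 6), "too short")

  const <- static_sequence(k = 5)
  expect_equal(average_frames(const, 5)$frame$pixels,
               selected_frame(const)$pixels)
})

test_that("fiber smoothing matches the closed-form Gaussian kernel", {
  f <- flat_frame(0.37)
  expect_equal(smooth_fiber_pattern(f, 0)$pixels, f$pixels)
  expect_equal(smooth_fiber_pattern(f, 1.5)$pixels, f$pixels,
               tolerance = 1e-12)                 # flat field invariant

  # unit impulse reproduces the normalized discrete Gaussian
  n <- 15L
  px <- matrix(0, n, n)
  px[8, 8] <- 1
  sigma <- 1
  out <- smooth_fiber_pattern(new_frame(px, tiny_params()), sigma)$pixels
  half <- ceiling(3 * sigma)
  w1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- outer(w1, w1)
  kern <- kern / sum(kern)
  expect_equal(out[8 + (-half):half, 8 + (-half):half], kern,
               tolerance = 1e-10)
  # mean preserved by circular convolution
  set.seed(9)
  g <- new_frame(matrix(runif(36^2), 36, 36), tiny_params())
  expect_equal(mean(smooth_fiber_pattern(g, 2)$pixels), mean(g$pixels),
               tolerance = 1e-3 * 0.1)
})

test_that("noise injection has the right scale and is seed-deterministic", {
  f <- flat_frame(0.5, n = 256)
  expect_identical(inject_noise(f, 0, 1)$pixels, f$pixels)
  out <- inject_noise(f, 0.05, seed = 3)
  expect_equal(sd(as.numeric(out$pixels - f$pixels)), 0.05, tolerance = 0.05)
  expect_identical(out$pixels, inject_noise(f, 0.05, seed = 3)$pixels)
  expect_false(identical(out$pixels, inject_noise(f, 0.05, seed = 4)$pixels))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("saturation preservation restores exactly the selected set", {
  set.seed(12)
  comp <- new_frame(matrix(runif(64, 0, 0.9), 8, 8), tiny_params())
  sel_px <- matrix(runif(64), 8, 8)
  sel_px[sel_px > 0.8] <- 1
  sel <- new_frame(sel_px, tiny_params())
  out <- preserve_saturation(comp, sel, saturation_level = 1)

  # brute-force pixel scan: changed set == selected frame's saturated set
  changed <- which(out$pixels != comp$pixels)
  expect_identical(changed, which(sel_px >= 1))
  expect_true(all(out$pixels[changed] == 1))

  none <- new_frame(matrix(0.3, 8, 8), tiny_params())
  expect_identical(preserve_saturation(comp, none)$pixels, comp$pixels)
  full <- new_frame(matrix(1, 8, 8), tiny_params())
  expect_identical(preserve_saturation(comp, full)$pixels, matrix(1, 8, 8))
  expect_error(preserve_saturation(comp, flat_frame(0.5, n = 4)), "shape")
})

test_that("luminance transfer hits the target stats exactly before clipping", {
  set.seed(5)
  px <- matrix(pmin(pmax(rnorm(400, 0.5, 0.1), 0), 1), 20, 20)
  f <- new_frame(px, tiny_params())
  out <- transfer_luminance_stats(f, luminance_stats(0.3, 0.05))
  expect_equal(mean(out$pixels), 0.3, tolerance = 1e-12)
  expect_equal(sd(as.numeric(out$pixels)), 0.05, tolerance = 1e-12)

  self <- transfer_luminance_stats(f, luminance_stats_of(f))
  expect_equal(self$pixels, px, tolerance = 1e-12)
  expect_error(transfer_luminance_stats(flat_frame(0.5), luminance_stats(0.3, 0.1)),
               "degenerate")
})

test_that("identity pipeline config returns the selected frame unchanged", {
  s <- static_sequence(k = 3)
  cfg <- degradation_config(n_average = 1,
                            enable_gamma_correction = FALSE,
                            enable_fiber_smoothing = FALSE,
                            enable_noise_injection = FALSE,
                            enable_saturation_preservation = FALSE,
                            enable_contrast_reduction = FALSE)
  out <- apply_method(s, cfg)
  expect_equal(out$pixels, selected_frame(s)$pixels)
})

test_that("ablation toggles control exactly their stage", {
  s <- static_sequence(k = 5, seed = 21)
  # Method 6 drops contrast reduction: stats are the composite's own
  out6 <- apply_method(s, degradation_method_config(6, noise_sigma = 0,
                                                    source_gamma = 1,
                                                    target_gamma = 1),
                       seed = 1)
  comp <- smooth_fiber_pattern(average_frames(s, 5)$frame, 1)
  expect_equal(mean(out6$pixels), mean(comp$pixels), tolerance = 1e-10)
  # with contrast reduction on, stats equal the target
  tgt <- luminance_stats(0.2, 0.04)
  out1 <- apply_method(s, degradation_method_config(1, noise_sigma = 0,
                                                    target_stats = tgt,
                                                    source_gamma = 1,
                                                    target_gamma = 1),
                       seed = 1)
  expect_equal(mean(out1$pixels), 0.2, tolerance = 1e-10)
  expect_equal(sd(as.numeric(out1$pixels)), 0.04, tolerance = 1e-10)
})

test_that("Method 1 and Method 2 differ only by gamma handling", {
  # gamma-encoded source sequence
  p <- tiny_params(gamma_exponent = 0.8)
  ph <- generate_phantom(c(600, 600), 400, seed = 8)
  s <- render_sequence(ph, trajectory_spec(0), p, 5, seed = 8, size_px = 32)
  base <- list(noise_sigma = 0, enable_contrast_reduction = FALSE,
               enable_fiber_smoothing = FALSE,
               enable_saturation_preservation = FALSE)
  m_gamma <- apply_method(s, do.call(degradation_method_config,
                                     c(list(method = 1, source_gamma = 0.8,
                                            target_gamma = 0.8), base)))
  m_nogamma <- apply_method(s, do.call(degradation_method_config,
                                       c(list(method = 2), base)))
  # static scene: averaging is identity, so gamma round-trip restores pixels
  expect_equal(m_gamma$pixels, m_nogamma$pixels, tolerance = 1e-10)

  # moving scene: averaging in linear vs encoded space genuinely differs
  s_mv <- render_sequence(ph, trajectory_spec(5), p, 5, seed = 8, size_px = 32)
  mv_gamma <- apply_method(s_mv, do.call(degradation_method_config,
                                         c(list(method = 1, source_gamma = 0.8,
                                                target_gamma = 0.8), base)))
  mv_nogamma <- apply_method(s_mv, do.call(degradation_method_config,
                                           c(list(method = 2), base)))
  expect_gt(max(abs(mv_gamma$pixels - mv_nogamma$pixels)), 1e-6)
})

test_that("pipeline preserves shape and is bit-deterministic", {
  s <- static_sequence(k = 5, seed = 30)
  for (m in 1:6) {
    out <- apply_method(s, degradation_method_config(m), seed = 7)
    expect_identical(dim(out$pixels), dim(selected_frame(s)$pixels))
    out2 <- apply_method(s, degradation_method_config(m), seed = 7)
    expect_identical(out$pixels, out2$pixels)
  }
})

test_that("blur extent of a moving edge grows with frames averaged", {
  # edge target: half-plane of nuclei-free bright region via custom phantom
  p <- tiny_params()
  nuc <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                    intensity = numeric(0))
  ph <- scene_phantom(nuc, c(2000, 2000), cytoplasm_intensity = 0.1)
  # paint a vertical bright strip by dense overlapping nuclei on one side
  xs <- seq(1010, 1990, by = 8)
  ys <- seq(10, 1990, by = 8)
  grid <- expand.grid(x = xs, y = ys)
  ph$nuclei <- data.frame(x = grid$x, y = grid$y, radius = 8, intensity = 0.9)
  s <- render_sequence(ph, trajectory_spec(10), p, 6, seed = 1, size_px = 48,
                       apply_mask = FALSE, apply_honeycomb = FALSE)
  edge_width <- function(frame) {
    prof <- colMeans(frame$pixels)
    lo <- min(prof) + 0.1 * diff(range(prof))
    hi <- min(prof) + 0.9 * diff(range(prof))
    sum(prof > lo & prof < hi)
  }
  w1 <- edge_width(average_frames(s, 1)$frame)
  w3 <- edge_width(average_frames(s, 3)$frame)
  w6 <- edge_width(average_frames(s, 6)$frame)
  expect_lt(w1, w3)
  expect_lt(w3, w6)
})

test_that("noise calibration yields the target blank noise-floor ratio", {
  expect_equal(calibrate_injected_noise(0.01, 5, 4), 0.01 * sqrt(16 - 0.2))
  # Monte-Carlo: blank sequence degraded with defaults -> 4x noise floor
  p <- tiny_params(noise_sigma = 0.01)
  blank <- scene_phantom(
    data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
               intensity = numeric(0)),
    c(3000, 3000), cytoplasm_intensity = 0.5, honeycomb_pitch = 3
  )
  s <- render_sequence(blank, trajectory_spec(0), p, 5, seed = 2,
                       size_px = 128, apply_mask = FALSE,
                       apply_honeycomb = FALSE)
  nf_in <- noise_floor(selected_frame(s))
  deg <- apply_method(s, degradation_method_config(
    2, enable_fiber_smoothing = FALSE, enable_contrast_reduction = FALSE
  ), seed = 3)
  expect_equal(noise_floor(deg) / nf_in, 4, tolerance = 0.1)
})
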