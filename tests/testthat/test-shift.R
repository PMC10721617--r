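test_that("feature extraction is a deterministic length-64 contract", {
  set.seed(6)
  q <- matrix(runif(400), 20, 20)
  v <- extract_features(q, 1)
  expect_length(v, 64)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_features(q, 1))
  expect_error(extract_features(q, 1, extractor = function(q, p) rep(1, 10)),
               "contract")
})

test_that("renderer classes are separable in feature space", {
  p <- tiny_params()
  render_q <- function(density, seed) {
    ph <- generate_phantom(c(600, 600), density,
                           nucleus_radius_range = c(4, 6), seed = seed)
    s <- render_sequence(ph, trajectory_spec(0), p, 1, seed = seed,
                         size_px = 64, apply_mask = FALSE,
                         apply_honeycomb = FALSE)
    selected_frame(s)$pixels
  }
  # dimension 35 (1-based) carries nucleus count density / 1000
  lo <- vapply(1:8, function(i) extract_features(render_q(150, i), 5)[35],
               numeric(1))
  hi <- vapply(1:8, function(i) extract_features(render_q(700, 100 + i), 5)[35],
               numeric(1))
  expect_lt(max(lo), min(hi))   # threshold on the density feature separates
})

test_that("gaussian KL estimator matches the closed form", {
  a <- gaussian_feature_set(200, 0, d = 4, label = "a", seed = 1)
  expect_lt(abs(estimate_kl(a, a)$value), 1e-12)

  # N(0,1) vs N(1,1): KL = 0.5 nats
  x <- gaussian_feature_set(1e5, 0, d = 1, seed = 2)
  y <- gaussian_feature_set(1e5, 1, d = 1, seed = 3)
  expect_equal(estimate_kl(x, y)$value, 0.5, tolerance = 0.05)

  # diagonal-Gaussian oracle: mean over dimensions of the closed form
  set.seed(4)
  mu_a <- c(0, 1, -1, 0.5); sd_a <- c(1, 2, 0.5, 1)
  mu_b <- c(0.5, 0, 0, 1);  sd_b <- c(1.5, 1, 1, 2)
  n <- 1e5
  A <- sapply(seq_len(4), function(j) rnorm(n, mu_a[j], sd_a[j]))
  B <- sapply(seq_len(4), function(j) rnorm(n, mu_b[j], sd_b[j]))
  oracle <- mean(log(sd_b / sd_a) +
                   (sd_a^2 + (mu_a - mu_b)^2) / (2 * sd_b^2) - 0.5)
  est <- estimate_kl(feature_set(A, "A"), feature_set(B, "B"))
  expect_equal(est$value, oracle, tolerance = 0.02 * oracle)
  expect_equal(est$value, mean(est$per_dimension))
  expect_gte(est$value, 0)
})

test_that("KL increases monotonically with mean shift at fixed variance", {
  base <- gaussian_feature_set(2000, 0, d = 2, seed = 10)
  kls <- vapply(c(0.25, 0.5, 1, 2), function(mu) {
    shifted <- gaussian_feature_set(2000, mu, d = 2, seed = 11)
    estimate_kl(shifted, base)$value
  }, numeric(1))
  expect_true(all(diff(kls) > 0))
})

test_that("zero-variance dimensions are floored, not fatal", {
  A <- cbind(rep(1, 10), rnorm(10))
  B <- cbind(rep(1, 10), rnorm(10))
  est <- estimate_kl(feature_set(A, "A"), feature_set(B, "B"))
  expect_true(is.finite(est$value))
  expect_error(estimate_kl(feature_set(A[1, , drop = FALSE], "A"),
                           feature_set(B, "B")), "at least 2")
})

test_that("knn estimator is sane on separated and identical distributions", {
  x <- gaussian_feature_set(300, 0, d = 2, seed = 20)
  y <- gaussian_feature_set(300, 3, d = 2, seed = 21)
  z <- gaussian_feature_set(300, 0, d = 2, seed = 22)
  kl_far <- estimate_kl(x, y, estimator = "knn")$value
  kl_same <- estimate_kl(x, z, estimator = "knn")$value
  expect_gt(kl_far, 1)
  expect_gt(kl_far, kl_same)
  expect_gt(kl_same, -0.05)    # small-sample tolerance for the knn form
})

test_that("2-D embedding separates distinct clusters and is reproducible", {
  a <- gaussian_feature_set(40, 0, sigma = 0.3, d = 8, label = "a", seed = 30)
  b <- gaussian_feature_set(40, 4, sigma = 0.3, d = 8, label = "b", seed = 31)
  emb <- embed_2d(list(a, b), perplexity = 8, seed = 5, max_iter = 250)
  expect_equal(nrow(emb), 80)
  # silhouette of the dataset labels on the embedding
  d <- as.matrix(dist(emb[, c("x", "y")]))
  sil <- vapply(seq_len(80), function(i) {
    own <- emb$label == emb$label[i]
    ai <- mean(d[i, own & seq_len(80) != i])
    bi <- mean(d[i, !own])
    (bi - ai) / max(ai, bi)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  emb2 <- embed_2d(list(a, b), perplexity = 8, seed = 5, max_iter = 250)
  expect_identical(emb, emb2)
  # single set runs
  single <- embed_2d(a, perplexity = 5, seed = 1, max_iter = 100)
  expect_equal(unique(single$label), "a")
  expect_error(embed_2d(a, perplexity = 20), "too few")
})

test_that("feature CSV round-trips", {
  fs <- gaussian_feature_set(5, 0, d = 64, label = "demo", seed = 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fs, path)
  back <- read_feature_csv(path)
  expect_equal(unname(back$vectors), unname(fs$vectors), tolerance = 1e-10)
  expect_equal(back$label, "demo")
})

test_that("degrading one arm toward the other reduces feature-set KL", {
  p <- tiny_params(gamma_exponent = 1, noise_sigma = 0.01)
  feats <- function(fr) {
    reg <- detect_probe_region(fr)
    q <- split_quadrants(fr, reg)
    t(vapply(q$quadrants, extract_features, numeric(64),
             pixel_pitch = q$pixel_pitch))
  }
  orig <- list(); degr <- list(); ref <- list()
  for (i in 1:6) {
    ph <- generate_phantom(c(700, 700), 400, seed = 50 + i)
    s <- render_sequence(ph, trajectory_spec(0.5), p, 5, seed = 60 + i,
                         size_px = 64)
    fr <- selected_frame(s)
    dg <- apply_method(s, degradation_method_config(2), seed = 70 + i)
    orig[[i]] <- feats(fr)
    degr[[i]] <- feats(dg)
    # "device B": an independently degraded rendering = the emulation target
    ph_b <- generate_phantom(c(700, 700), 400, seed = 150 + i)
    s_b <- render_sequence(ph_b, trajectory_spec(0.5), p, 5, seed = 160 + i,
                           size_px = 64)
    ref[[i]] <- feats(apply_method(s_b, degradation_method_config(2),
                                   seed = 170 + i))
  }
  A <- feature_set(do.call(rbind, orig), "device_A")
  A_deg <- feature_set(do.call(rbind, degr), "device_A_degraded")
  B <- feature_set(do.call(rbind, ref), "device_B")
  expect_lt(estimate_kl(A_deg, B)$value, estimate_kl(A, B)$value)
})
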