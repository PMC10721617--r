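#' Luminance statistics of an image
#'
#' Target mean and standard deviation for luminance-statistics transfer
#' (grayscale color transfer), on normalized \[0, 1\] intensity.
#'
#' @param mean,std Target mean and standard deviation; `std >= 0`.
#' @return An object of class `luminance_stats`.
#' @export
luminance_stats <- function(mean, std) {
  if (std < 0) stop("`std` must be >= 0", call. = FALSE)
  structure(list(mean = mean, std = std), class = "luminance_stats")
}

#' @rdname luminance_stats
#' @param frame An `hrme_frame` whose pixel mean/sd are measured.
#' @export
luminance_stats_of <- function(frame) {
  stopifnot(inherits(frame, "hrme_frame"))
  luminance_stats(mean(frame$pixels), stats::sd(as.numeric(frame$pixels)))
}

#' Invert / apply gamma encoding
#'
#' `linearize()` converts a gamma-encoded frame to linear intensity by
#' raising the normalized pixels to `1/gamma`; `encode_gamma()` applies the
#' encoding by raising linear pixels to `gamma`. Both are exact inverses of
#' one another, monotone for any `gamma > 0`, and the identity at `gamma = 1`.
#'
#' @param frame An `hrme_frame`.
#' @param gamma Positive gamma exponent.
#' @return The transformed `hrme_frame` with its `gamma_encoded` flag updated.
#' @export
linearize <- function(frame, gamma) {
  stopifnot(inherits(frame, "hrme_frame"))
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (!frame$gamma_encoded) stop("frame is not gamma encoded", call. = FALSE)
  frame$pixels <- frame$pixels^(1 / gamma)
  frame$gamma_encoded <- FALSE
  frame
}

#' @rdname linearize
#' @export
encode_gamma <- function(frame, gamma) {
  stopifnot(inherits(frame, "hrme_frame"))
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (frame$gamma_encoded) stop("frame is already gamma encoded", call. = FALSE)
  frame$pixels <- frame$pixels^gamma
  frame$gamma_encoded <- TRUE
  frame
}

#' Average the selected frame with its predecessors
#'
#' Simulates a slower camera: the pixelwise arithmetic mean of the clinically
#' selected frame and its `n - 1` immediate predecessors behaves like a
#' single frame whose exposure is `n` times longer, captured by a system
#' running at `frame_rate / n`. With the 70 fps / 1.4 ms source and `n = 5`
#' this yields a 7 ms composite equivalent to a 14 fps system.
#'
#' @param seq An `hrme_sequence`; the selected frame must have at least
#'   `n - 1` predecessors. Frames are expected in linear space.
#' @param n Number of frames to average (>= 1).
#' @return A list with elements `frame` (the composite `hrme_frame`),
#'   `equivalent_frame_rate` (fps) and `composite_exposure` (ms).
#' @export
average_frames <- function(seq, n = 5L) {
  stopifnot(inherits(seq, "hrme_sequence"))
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (seq$selected_index < n) {
    stop(sprintf(
      "sequence too short: selected frame has %d predecessor(s), need %d",
      seq$selected_index - 1L, n - 1L), call. = FALSE)
  }
  idx <- (seq$selected_index - n + 1L):seq$selected_index
  acc <- Reduce(`+`, lapply(seq$frames[idx], function(f) f$pixels))
  comp <- seq$frames[[seq$selected_index]]
  comp$pixels <- acc / n
  list(
    frame = comp,
    equivalent_frame_rate = seq$params$frame_rate / n,
    composite_exposure = n * seq$params$exposure
  )
}

#' Soften the honeycomb fiber-core pattern
#'
#' Convolution with a normalized isotropic Gaussian kernel (circular
#' boundary, so the image mean is preserved exactly). `sigma = 0` is the
#' identity. The kernel is small by design: its purpose is to suppress the
#' core lattice that frame averaging reinforces, not to further blur tissue
#' structure.
#'
#' @param frame An `hrme_frame`.
#' @param sigma Kernel standard deviation in pixels (>= 0); default 1.
#' @return The smoothed `hrme_frame`.
#' @export
smooth_fiber_pattern <- function(frame, sigma = 1) {
  stopifnot(inherits(frame, "hrme_frame"))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  frame$pixels <- gaussian_smooth(frame$pixels, sigma)
  frame
}

#' Inject additive sensor noise
#'
#' Adds zero-mean Gaussian noise (standard deviation `noise_sigma` as a
#' fraction of full scale) and clips to \[0, 1\]. Deterministic given `seed`.
#'
#' @param frame An `hrme_frame`.
#' @param noise_sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The noisy `hrme_frame`.
#' @export
inject_noise <- function(frame, noise_sigma, seed = 1L) {
  stopifnot(inherits(frame, "hrme_frame"))
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma == 0) return(frame)
  d <- dim(frame$pixels)
  withr_seed(seed, {
    frame$pixels <- pmin(pmax(
      frame$pixels + matrix(stats::rnorm(prod(d), 0, noise_sigma), d[1], d[2]),
      0), 1)
  })
  frame
}

#' Preserve the selected frame's saturated pixels in the composite
#'
#' Frame averaging dampens saturation; this restores it: every pixel at or
#' above `saturation_level` in the clinically selected frame is forced to
#' full scale in the composite, all other pixels are left unchanged.
#'
#' @param composite,selected `hrme_frame`s of identical raster shape.
#' @param saturation_level Saturation threshold on normalized intensity.
#' @return The composite `hrme_frame` with saturation restored.
#' @export
preserve_saturation <- function(composite, selected,
                                saturation_level = 1) {
  stopifnot(inherits(composite, "hrme_frame"), inherits(selected, "hrme_frame"))
  if (!identical(dim(composite$pixels), dim(selected$pixels))) {
    stop("composite and selected frames must have the same shape", call. = FALSE)
  }
  sat <- selected$pixels >= saturation_level
  composite$pixels[sat] <- 1
  composite
}

#' Transfer luminance statistics (grayscale color transfer)
#'
#' Standardizes the frame by its own mean and standard deviation, then
#' rescales and shifts to the target statistics:
#' `out = (in - mean(in)) / sd(in) * target$std + target$mean`, clipped to
#' \[0, 1\]. Before clipping, the output mean and standard deviation equal
#' the targets exactly. On a single-channel image the CIELAB luminance
#' channel is a monotone function of intensity, so the transfer is applied
#' directly on normalized intensity, which keeps the mean/std contract exact.
#'
#' @param frame An `hrme_frame` with nonzero intensity standard deviation.
#' @param target A [luminance_stats()] object.
#' @return The remapped `hrme_frame`.
#' @export
transfer_luminance_stats <- function(frame, target) {
  stopifnot(inherits(frame, "hrme_frame"), inherits(target, "luminance_stats"))
  s <- stats::sd(as.numeric(frame$pixels))
  if (s == 0) {
    stop("degenerate input: frame has zero intensity variance", call. = FALSE)
  }
  m <- mean(frame$pixels)
  frame$pixels <- pmin(pmax(
    (frame$pixels - m) / s * target$std + target$mean, 0), 1)
  frame
}

#' Degradation pipeline configuration
#'
#' Toggles and parameters for the five transformation components of the
#' frame-rate/contrast degradation pipeline (plus the always-on frame
#' averaging): gamma handling, fiber-core smoothing, noise injection,
#' saturation preservation, and contrast reduction by luminance-statistics
#' transfer.
#'
#' @param n_average Frames averaged into the composite (>= 1); default 5.
#' @param enable_gamma_correction Invert the source gamma before averaging
#'   and re-apply the target gamma after.
#' @param enable_fiber_smoothing Apply the small Gaussian core smoothing.
#' @param enable_noise_injection Add sensor noise to the composite.
#' @param enable_saturation_preservation Restore the selected frame's
#'   saturated pixels.
#' @param enable_contrast_reduction Apply luminance-statistics transfer.
#' @param source_gamma,target_gamma Gamma exponents of the source and target
#'   cameras (no manufacturer values are published; configuration).
#' @param smoothing_sigma Core smoothing sigma in pixels.
#' @param noise_sigma Injected noise sigma; `NULL` calibrates it with
#'   [calibrate_injected_noise()] so a degraded blank frame's noise floor is
#'   four times the source's.
#' @param saturation_level Saturation threshold on normalized intensity.
#' @param target_stats A [luminance_stats()] target for contrast reduction.
#' @return An object of class `degradation_config`.
#' @export
degradation_config <- function(n_average = 5L,
                               enable_gamma_correction = TRUE,
                               enable_fiber_smoothing = TRUE,
                               enable_noise_injection = TRUE,
                               enable_saturation_preservation = TRUE,
                               enable_contrast_reduction = TRUE,
                               source_gamma = 0.8,
                               target_gamma = 0.8,
                               smoothing_sigma = 1,
                               noise_sigma = NULL,
                               saturation_level = 1,
                               target_stats = luminance_stats(0.16, 0.055)) {
  if (n_average < 1L) stop("`n_average` must be >= 1", call. = FALSE)
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0", call. = FALSE)
  if (!is.null(noise_sigma) && noise_sigma < 0) {
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  }
  if (saturation_level <= 0 || saturation_level > 1) {
    stop("`saturation_level` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_average = as.integer(n_average),
         enable_gamma_correction = enable_gamma_correction,
         enable_fiber_smoothing = enable_fiber_smoothing,
         enable_noise_injection = enable_noise_injection,
         enable_saturation_preservation = enable_saturation_preservation,
         enable_contrast_reduction = enable_contrast_reduction,
         source_gamma = source_gamma, target_gamma = target_gamma,
         smoothing_sigma = smoothing_sigma, noise_sigma = noise_sigma,
         saturation_level = saturation_level, target_stats = target_stats),
    class = "degradation_config"
  )
}

#' Injected-noise sigma for a target blank noise-floor ratio
#'
#' Averaging `n` frames divides the source noise variance by `n`; injecting
#' independent noise of sigma `s` gives a composite noise floor
#' `sqrt(s^2 + input_sigma^2 / n)`. Solving for a composite floor of
#' `ratio * input_sigma` gives `s = input_sigma * sqrt(ratio^2 - 1/n)`. The
#' default ratio 4 matches the blank-target measurement that the slower
#' camera's noise floor is four times the fast camera's.
#'
#' @param input_sigma Source per-frame noise sigma.
#' @param n_average Frames averaged.
#' @param ratio Target composite/source noise-floor ratio.
#' @return The injected-noise sigma.
#' @export
calibrate_injected_noise <- function(input_sigma, n_average = 5L, ratio = 4) {
  if (ratio^2 < 1 / n_average) {
    stop("`ratio` too small: averaging alone already exceeds it", call. = FALSE)
  }
  input_sigma * sqrt(ratio^2 - 1 / n_average)
}

#' Ablation-method configurations
#'
#' The ablation harness defines six methods: Method 1 enables all five
#' transformation components; Methods 2-5 disable one blur-synthesis
#' component each (2: gamma correction, 3: fiber-core smoothing, 4: noise
#' injection, 5: saturation preservation); Method 6 disables contrast
#' reduction. Frame averaging always runs.
#'
#' @param method Integer in 1..6.
#' @param ... Parameter overrides forwarded to [degradation_config()].
#' @return A `degradation_config`.
#' @export
degradation_method_config <- function(method, ...) {
  if (!method %in% 1:6) stop("`method` must be in 1..6", call. = FALSE)
  toggles <- list()
  if (method == 2L) toggles$enable_gamma_correction <- FALSE
  if (method == 3L) toggles$enable_fiber_smoothing <- FALSE
  if (method == 4L) toggles$enable_noise_injection <- FALSE
  if (method == 5L) toggles$enable_saturation_preservation <- FALSE
  if (method == 6L) toggles$enable_contrast_reduction <- FALSE
  do.call(degradation_config, utils::modifyList(toggles, list(...)))
}

#' Run the degradation pipeline on a frame sequence
#'
#' Executes, in order: optional gamma inversion of each contributing frame,
#' frame averaging (always), optional fiber-core smoothing, optional noise
#' injection, optional saturation preservation (saturation measured on the
#' clinically selected frame), optional gamma re-encoding, and optional
#' contrast reduction by luminance-statistics transfer. With every toggle
#' off and `n_average = 1` the pipeline is the identity on the selected
#' frame. Bit-identical output is guaranteed for identical sequence, config
#' and seed.
#'
#' @param seq An `hrme_sequence`.
#' @param config A [degradation_config()].
#' @param seed Integer seed for the noise-injection stage.
#' @return The degraded composite `hrme_frame`; attributes
#'   `equivalent_frame_rate` and `composite_exposure` carry the averaging
#'   bookkeeping.
#' @export
apply_method <- function(seq, config, seed = 1L) {
  stopifnot(inherits(seq, "hrme_sequence"), inherits(config, "degradation_config"))
  selected_raw <- selected_frame(seq)
  work <- seq
  if (config$enable_gamma_correction) {
    work$frames <- lapply(work$frames, function(f) {
      if (f$gamma_encoded) linearize(f, config$source_gamma) else f
    })
  }
  avg <- average_frames(work, config$n_average)
  out <- avg$frame
  if (config$enable_fiber_smoothing) {
    out <- smooth_fiber_pattern(out, config$smoothing_sigma)
  }
  if (config$enable_noise_injection) {
    ns <- config$noise_sigma
    if (is.null(ns)) {
      ns <- calibrate_injected_noise(seq$params$noise_sigma, config$n_average)
    }
    out <- inject_noise(out, ns, seed)
  }
  if (config$enable_saturation_preservation) {
    out <- preserve_saturation(out, selected_raw, config$saturation_level)
  }
  if (config$enable_gamma_correction && !out$gamma_encoded) {
    out <- encode_gamma(out, config$target_gamma)
  }
  if (config$enable_contrast_reduction) {
    out <- transfer_luminance_stats(out, config$target_stats)
  }
  attr(out, "equivalent_frame_rate") <- avg$equivalent_frame_rate
  attr(out, "composite_exposure") <- avg$composite_exposure
  out
}
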