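#' Acquisition parameters for a fiber-bundle microendoscope
#'
#' Bundles the camera and optics constants that the renderer, degradation
#' pipeline and scorer need: frame rate, per-frame exposure, spatial sampling
#' (pixel pitch), circular field-of-view diameter, lateral resolution, bit
#' depth, the camera's gamma encoding exponent, additive sensor noise and the
#' saturation level.
#'
#' @param frame_rate Frames per second (> 0).
#' @param exposure Per-frame exposure in milliseconds; must not exceed the
#'   frame period `1000 / frame_rate`.
#' @param pixel_pitch Micrometers per pixel at the tissue interface (> 0).
#' @param fov_diameter Diameter of the illuminated circular field of view in
#'   micrometers.
#' @param lateral_resolution Lateral optical resolution in micrometers.
#' @param bit_depth Sensor bit depth (integer, e.g. 8 or 16).
#' @param gamma_exponent Exponent of the camera's gamma encoding; 1 means
#'   linear output. No manufacturer value is published for either HRME
#'   camera, so this is configuration with a linear default.
#' @param noise_sigma Standard deviation of additive zero-mean Gaussian
#'   sensor noise, as a fraction of full scale (>= 0).
#' @param saturation_level Intensity fraction at or above which a pixel is
#'   considered saturated; in (0, 1].
#'
#' @return An object of class `acquisition_params`.
#' @seealso [hf_hrme_params()], [original_hrme_params()]
#' @export
acquisition_params <- function(frame_rate,
                               exposure,
                               pixel_pitch,
                               fov_diameter = 790,
                               lateral_resolution = 4,
                               bit_depth = 16L,
                               gamma_exponent = 1,
                               noise_sigma = 0.01,
                               saturation_level = 1) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L)
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  if (exposure <= 0) stop("`exposure` must be positive", call. = FALSE)
  if (exposure > 1000 / frame_rate + 1e-9) {
    stop("`exposure` exceeds the frame period 1000/frame_rate ms", call. = FALSE)
  }
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive", call. = FALSE)
  if (fov_diameter <= 0) stop("`fov_diameter` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (saturation_level <= 0 || saturation_level > 1) {
    stop("`saturation_level` must lie in (0, 1]", call. = FALSE)
  }
  if (gamma_exponent <= 0) stop("`gamma_exponent` must be positive", call. = FALSE)
  structure(
    list(
      frame_rate = frame_rate,
      exposure = exposure,
      pixel_pitch = pixel_pitch,
      fov_diameter = fov_diameter,
      lateral_resolution = lateral_resolution,
      bit_depth = as.integer(bit_depth),
      gamma_exponent = gamma_exponent,
      noise_sigma = noise_sigma,
      saturation_level = saturation_level
    ),
    class = "acquisition_params"
  )
}

#' High-frame-rate HRME acquisition constants
#'
#' 70 fps, 1.4 ms exposure, 1.24 um/px sampling, 790 um field of view, 4 um
#' lateral resolution — the CMOS-camera configuration of the high-frame-rate
#' device. Optional camera metadata (dynamic range 74.35 dB, temporal dark
#' noise 3.8 e-) is attached as an attribute for reference.
#'
#' @param ... Overrides passed to [acquisition_params()].
#' @return An `acquisition_params` object.
#' @export
hf_hrme_params <- function(...) {
  p <- utils::modifyList(
    list(frame_rate = 70, exposure = 1.4, pixel_pitch = 1.24,
         fov_diameter = 790, lateral_resolution = 4, bit_depth = 16L,
         gamma_exponent = 1, noise_sigma = 0.01, saturation_level = 1),
    list(...)
  )
  out <- do.call(acquisition_params, p)
  attr(out, "camera") <- list(dynamic_range_db = 74.35, temporal_dark_noise_e = 3.8)
  out
}

#' Original (low frame rate) HRME acquisition constants
#'
#' 15 fps CCD camera with 0.78 um/px sampling. Exposure defaults to the frame
#' period fraction used for simulation; camera metadata (dynamic range
#' 57.85 dB, temporal dark noise 7.65 e-) is attached as an attribute.
#'
#' @param ... Overrides passed to [acquisition_params()].
#' @return An `acquisition_params` object.
#' @export
original_hrme_params <- function(...) {
  p <- utils::modifyList(
    list(frame_rate = 15, exposure = 7, pixel_pitch = 0.78,
         fov_diameter = 790, lateral_resolution = 4, bit_depth = 8L,
         gamma_exponent = 1, noise_sigma = 0.04, saturation_level = 1),
    list(...)
  )
  out <- do.call(acquisition_params, p)
  attr(out, "camera") <- list(dynamic_range_db = 57.85, temporal_dark_noise_e = 7.65)
  out
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> %g fps, %g ms exposure, %g um/px, FOV %g um, %d-bit\n",
    x$frame_rate, x$exposure, x$pixel_pitch, x$fov_diameter, x$bit_depth
  ))
  invisible(x)
}

#' Construct a single microendoscopy frame
#'
#' A frame is a square matrix of normalized intensities in \[0, 1\] plus the
#' acquisition parameters it was captured with, a timestamp and a flag saying
#' whether the pixel values are gamma encoded. All package arithmetic runs on
#' normalized floating-point intensities; quantization to the bit depth
#' happens only when a frame is written to disk.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\].
#' @param params An [acquisition_params()] object.
#' @param timestamp Acquisition time in milliseconds.
#' @param gamma_encoded Logical flag; `TRUE` if `pixels` are gamma encoded.
#' @return An object of class `hrme_frame`.
#' @export
new_frame <- function(pixels, params, timestamp = 0, gamma_encoded = FALSE) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) != ncol(pixels)) stop("frame raster must be square", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1 + 1e-12) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(params, "acquisition_params")) {
    stop("`params` must be an acquisition_params object", call. = FALSE)
  }
  structure(
    list(pixels = pixels, params = params, timestamp = timestamp,
         gamma_encoded = isTRUE(gamma_encoded)),
    class = "hrme_frame"
  )
}

#' @export
print.hrme_frame <- function(x, ...) {
  cat(sprintf("<hrme_frame> %dx%d px, t = %g ms, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$timestamp,
              if (x$gamma_encoded) "gamma encoded" else "linear"))
  invisible(x)
}

#' @export
as.matrix.hrme_frame <- function(x, ...) x$pixels

#' Construct a frame sequence
#'
#' An ordered burst of frames sharing acquisition parameters, with one frame
#' marked as the clinically selected frame. Timestamps must increase by the
#' frame period `1000 / frame_rate` ms.
#'
#' @param frames List of [new_frame()] objects.
#' @param selected_index 1-based index of the clinically selected frame.
#' @return An object of class `hrme_sequence`.
#' @export
new_sequence <- function(frames, selected_index = length(frames)) {
  if (length(frames) < 1L) stop("a sequence needs at least one frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "hrme_frame"))) {
    stop("all elements must be hrme_frame objects", call. = FALSE)
  }
  if (selected_index < 1L || selected_index > length(frames)) {
    stop("`selected_index` out of range", call. = FALSE)
  }
  period <- 1000 / frames[[1L]]$params$frame_rate
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L && any(abs(diff(ts) - period) > 1e-6 * period)) {
    stop("timestamps must increase by the frame period", call. = FALSE)
  }
  structure(
    list(frames = frames, selected_index = as.integer(selected_index),
         params = frames[[1L]]$params),
    class = "hrme_sequence"
  )
}

#' @export
print.hrme_sequence <- function(x, ...) {
  cat(sprintf("<hrme_sequence> %d frames at %g fps, selected frame %d\n",
              length(x$frames), x$params$frame_rate, x$selected_index))
  invisible(x)
}

#' @export
length.hrme_sequence <- function(x) length(x$frames)

#' Selected frame of a sequence
#' @param seq An `hrme_sequence`.
#' @return The clinically selected `hrme_frame`.
#' @export
selected_frame <- function(seq) {
  stopifnot(inherits(seq, "hrme_sequence"))
  seq$frames[[seq$selected_index]]
}
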