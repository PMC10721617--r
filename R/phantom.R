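#' Scene phantom: bright nuclei on dim cytoplasm
#'
#' A ground-truth description of a proflavine-like fluorescence scene as seen
#' through a fiber bundle: nuclei are discrete bright disks on a dim
#' cytoplasmic background, and the bundle superimposes a hexagonal (honeycomb)
#' core transmission pattern. Coordinates and sizes are in micrometers so the
#' same phantom can be rendered at any pixel pitch.
#'
#' @param nuclei Data frame with columns `x`, `y` (um, within the extent),
#'   `radius` (um, > 0) and `intensity` (fraction of full scale in (0, 1]).
#' @param extent Numeric length-2, phantom width and height in micrometers.
#' @param cytoplasm_intensity Background intensity fraction.
#' @param honeycomb_pitch Fiber core spacing in micrometers; should not be
#'   below the lateral resolution of the device that will image the phantom.
#' @return An object of class `scene_phantom`.
#' @export
scene_phantom <- function(nuclei, extent,
                          cytoplasm_intensity = 0.15,
                          honeycomb_pitch = 3) {
  stopifnot(is.data.frame(nuclei),
            all(c("x", "y", "radius", "intensity") %in% names(nuclei)))
  if (any(extent <= 0)) stop("`extent` must be positive", call. = FALSE)
  if (length(extent) == 1L) extent <- c(extent, extent)
  if (nrow(nuclei) > 0L) {
    if (any(nuclei$radius <= 0)) stop("nucleus radii must be > 0", call. = FALSE)
    if (any(nuclei$intensity <= 0 | nuclei$intensity > 1)) {
      stop("nucleus intensities must lie in (0, 1]", call. = FALSE)
    }
    inside <- nuclei$x >= 0 & nuclei$x <= extent[1] &
      nuclei$y >= 0 & nuclei$y <= extent[2]
    if (!all(inside)) stop("all nuclei must lie within the extent", call. = FALSE)
  }
  structure(
    list(nuclei = nuclei, extent = extent,
         cytoplasm_intensity = cytoplasm_intensity,
         honeycomb_pitch = honeycomb_pitch),
    class = "scene_phantom"
  )
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf("<scene_phantom> %d nuclei over %g x %g um, cytoplasm %.2f\n",
              nrow(x$nuclei), x$extent[1], x$extent[2], x$cytoplasm_intensity))
  invisible(x)
}

#' Generate a random scene phantom
#'
#' Nuclei are placed by a homogeneous Poisson process (overlaps permitted)
#' with radii and intensities drawn uniformly from the given ranges. The
#' phantom is fully determined by `seed`, and the nucleus list is retained as
#' ground truth for downstream classifier checks.
#'
#' @param extent Phantom width/height in micrometers (scalar or length 2).
#' @param nucleus_density Expected nuclei per square millimeter (>= 0).
#' @param nucleus_radius_range Length-2 positive increasing range, um.
#' @param intensity_range Length-2 range in (0, 1].
#' @param cytoplasm_intensity Background intensity fraction.
#' @param honeycomb_pitch Fiber core spacing, um.
#' @param seed Integer seed; same seed reproduces the same phantom.
#' @return A [scene_phantom()].
#' @examples
#' ph <- generate_phantom(400, nucleus_density = 300, seed = 1)
#' nrow(ph$nuclei)
#' @export
generate_phantom <- function(extent,
                             nucleus_density,
                             nucleus_radius_range = c(3, 6),
                             intensity_range = c(0.6, 0.95),
                             cytoplasm_intensity = 0.15,
                             honeycomb_pitch = 3,
                             seed = 1L) {
  if (any(extent <= 0)) stop("`extent` must be positive", call. = FALSE)
  if (length(extent) == 1L) extent <- c(extent, extent)
  if (nucleus_density < 0) stop("`nucleus_density` must be >= 0", call. = FALSE)
  if (length(nucleus_radius_range) != 2L ||
      any(nucleus_radius_range <= 0) || diff(nucleus_radius_range) < 0) {
    stop("`nucleus_radius_range` must be positive and ordered", call. = FALSE)
  }
  area_mm2 <- prod(extent) / 1e6
  withr_seed(seed, {
    n <- stats::rpois(1L, nucleus_density * area_mm2)
    nuclei <- data.frame(
      x = stats::runif(n, 0, extent[1]),
      y = stats::runif(n, 0, extent[2]),
      radius = stats::runif(n, nucleus_radius_range[1], nucleus_radius_range[2]),
      intensity = stats::runif(n, intensity_range[1], intensity_range[2])
    )
  })
  scene_phantom(nuclei, extent, cytoplasm_intensity, honeycomb_pitch)
}

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(code))
}

#' Probe trajectory during a frame burst
#'
#' Straight-line translation at constant speed. 15 mm/s is the fastest
#' translation the high-frame-rate device tolerates in practice and is the
#' natural upper end for simulations.
#'
#' @param speed Probe translation speed in millimeters per second (>= 0).
#' @param direction Length-2 direction vector; normalized internally.
#' @param duration Duration in seconds (used by [run_pipeline()] configs;
#'   rendering takes the frame count explicitly).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(speed, direction = c(1, 0), duration = NULL) {
  if (speed < 0) stop("`speed` must be >= 0", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be nonzero", call. = FALSE)
  structure(list(speed = speed, direction = direction / nrm,
                 duration = duration),
            class = "trajectory_spec")
}

# analytic anti-aliased rendering of the phantom at a probe-center offset;
# returns a linear-intensity matrix (rows = y, cols = x), no PSF/mask yet
render_scene_raw <- function(phantom, params, center_um, size_px) {
  pitch <- params$pixel_pitch
  img <- matrix(phantom$cytoplasm_intensity, size_px, size_px)
  # pixel-center scene coordinates
  half <- (size_px - 1) / 2
  xs <- center_um[1] + (seq_len(size_px) - 1 - half) * pitch
  ys <- center_um[2] + (seq_len(size_px) - 1 - half) * pitch
  nuc <- phantom$nuclei
  if (nrow(nuc) == 0L) return(img)
  for (i in seq_len(nrow(nuc))) {
    r_px <- nuc$radius[i] / pitch
    ci <- findInterval(nuc$x[i], xs)
    ri <- findInterval(nuc$y[i], ys)
    w <- ceiling(r_px) + 2L
    cols <- max(1L, ci - w):min(size_px, ci + w)
    rows <- max(1L, ri - w):min(size_px, ri + w)
    if (!length(cols) || !length(rows)) next
    dx <- (xs[cols] - nuc$x[i]) / pitch
    dy <- (ys[rows] - nuc$y[i]) / pitch
    d <- sqrt(outer(dy^2, dx^2, `+`))
    cov <- pmin(pmax(r_px - d + 0.5, 0), 1)   # anti-aliased disk coverage
    blk <- img[rows, cols, drop = FALSE]
    img[rows, cols] <- blk + cov * (nuc$intensity[i] - blk)
  }
  img
}

# hexagonal-lattice multiplicative transmission map of the fiber bundle
honeycomb_map <- function(size_px, pitch_px, min_transmission = 0.6) {
  k <- 4 * pi / (sqrt(3) * pitch_px)
  idx <- seq_len(size_px) - (size_px + 1) / 2
  x <- matrix(idx, size_px, size_px, byrow = TRUE)
  y <- matrix(idx, size_px, size_px)
  f <- cos(k * x) + cos(k * (x / 2 + sqrt(3) * y / 2)) +
    cos(k * (x / 2 - sqrt(3) * y / 2))
  g <- (f + 1.5) / 4.5                      # to [0, 1]
  min_transmission + (1 - min_transmission) * g
}

# circular field-of-view mask (TRUE inside)
fov_mask <- function(size_px, radius_px = size_px / 2) {
  idx <- seq_len(size_px) - (size_px + 1) / 2
  x <- matrix(idx, size_px, size_px, byrow = TRUE)
  y <- matrix(idx, size_px, size_px)
  x^2 + y^2 <= radius_px^2
}

gaussian_brush <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  EBImage::makeBrush(2L * half + 1L, shape = "gaussian", sigma = sigma)
}

# Gaussian smoothing with circular boundary (mean-preserving)
gaussian_smooth <- function(pixels, sigma) {
  if (sigma <= 0) return(pixels)
  as.matrix(EBImage::filter2(pixels, gaussian_brush(sigma), boundary = "circular"))
}

#' Render a frame sequence of a moving probe over a phantom
#'
#' Each frame integrates the scene over its exposure window along the
#' trajectory (within-exposure blur extent = speed x exposure), so a probe
#' moving at 5 mm/s with a 1.4 ms exposure smears the scene by 7 um within a
#' frame, and consecutive frames are offset by speed / frame_rate. The frame
#' is then blurred by a Gaussian resolution kernel (FWHM = the device's
#' lateral resolution), modulated by the honeycomb core pattern, masked to
#' the circular field of view, given additive Gaussian sensor noise in linear
#' space (clipped to \[0, 1\]), and finally gamma encoded when the device's
#' `gamma_exponent` differs from 1.
#'
#' Noise for frame `i` uses the deterministic substream `seed + i`, so a
#' sequence is bit-reproducible given `seed`.
#'
#' @param phantom A [scene_phantom()].
#' @param trajectory A [trajectory_spec()]. The path is centered on the
#'   phantom; if the field of view would leave the phantom extent during the
#'   burst an out-of-bounds error is raised.
#' @param params An [acquisition_params()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer master seed for the per-frame noise substreams.
#' @param size_px Raster side in pixels; defaults to
#'   `round(fov_diameter / pixel_pitch)`.
#' @param apply_mask,apply_honeycomb Logical; disable to inspect the
#'   unmasked/unmodulated blur integral (used by flux-conservation checks).
#' @return An `hrme_sequence` with the last frame selected.
#' @export
render_sequence <- function(phantom, trajectory, params, n_frames,
                            seed = 1L, size_px = NULL,
                            apply_mask = TRUE, apply_honeycomb = TRUE) {
  stopifnot(inherits(phantom, "scene_phantom"),
            inherits(trajectory, "trajectory_spec"),
            inherits(params, "acquisition_params"))
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  if (is.null(size_px)) size_px <- round(params$fov_diameter / params$pixel_pitch)
  period_ms <- 1000 / params$frame_rate
  speed_um_ms <- trajectory$speed            # mm/s == um/ms
  travel <- speed_um_ms * ((n_frames - 1L) * period_ms + params$exposure)
  start <- phantom$extent / 2 - trajectory$direction * travel / 2
  half_fov <- size_px * params$pixel_pitch / 2
  ends <- rbind(start, start + trajectory$direction * travel)
  lo <- apply(ends, 2, min) - half_fov
  hi <- apply(ends, 2, max) + half_fov
  if (any(lo < -1e-9) || any(hi > phantom$extent + 1e-9)) {
    stop("trajectory carries the field of view outside the phantom extent",
         call. = FALSE)
  }
  psf_sigma_px <- params$lateral_resolution / 2.355 / params$pixel_pitch
  hc <- if (apply_honeycomb) {
    honeycomb_map(size_px, phantom$honeycomb_pitch / params$pixel_pitch)
  } else NULL
  msk <- if (apply_mask) fov_mask(size_px) else NULL

  blur_um <- speed_um_ms * params$exposure
  n_sub <- max(1L, min(15L, ceiling(2 * blur_um / params$pixel_pitch)))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t0 <- (i - 1L) * period_ms
    acc <- matrix(0, size_px, size_px)
    for (j in seq_len(n_sub)) {
      tj <- t0 + params$exposure * (j - 0.5) / n_sub
      ctr <- start + trajectory$direction * speed_um_ms * tj
      acc <- acc + render_scene_raw(phantom, params, ctr, size_px)
    }
    px <- acc / n_sub
    px <- gaussian_smooth(px, psf_sigma_px)
    if (!is.null(hc)) px <- px * hc
    if (!is.null(msk)) px[!msk] <- 0
    if (params$noise_sigma > 0) {
      withr_seed(seed + i, {
        px <- px + matrix(stats::rnorm(size_px^2, 0, params$noise_sigma),
                          size_px, size_px)
      })
    }
    px <- pmin(pmax(px, 0), 1)
    encoded <- params$gamma_exponent != 1
    if (encoded) px <- px^params$gamma_exponent
    frames[[i]] <- new_frame(px, params, timestamp = t0, gamma_encoded = encoded)
  }
  new_sequence(frames, selected_index = n_frames)
}
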