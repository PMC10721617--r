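#' Detect the illuminated probe region in a frame
#'
#' The fiber-optic probe appears as a bright disk on a dark background. The
#' detector thresholds the frame (Otsu), keeps the largest connected
#' component, and reports its centroid and equivalent radius
#' (`sqrt(area / pi)`) together with the inscribing bounding square (0-based,
#' half-open, clamped to the raster).
#'
#' @param frame An `hrme_frame`.
#' @param min_area_fraction Minimum fraction of the raster the component must
#'   cover; below this a probe-not-found error is raised.
#' @return An object of class `probe_region` with fields `center` (x, y in
#'   0-based pixel coordinates), `radius` (pixels) and `bounding_square`
#'   (`x0`, `y0`, `x1`, `y1`, half-open).
#' @export
detect_probe_region <- function(frame, min_area_fraction = 0.05) {
  stopifnot(inherits(frame, "hrme_frame"))
  px <- frame$pixels
  # homogenize cellular texture so Otsu separates lit vs unlit rather than
  # nuclei vs cytoplasm
  px_s <- gaussian_smooth(px, sigma = nrow(px) / 12)
  if (diff(range(px_s)) < 1e-6) {
    # uniform frame: fully illuminated or fully dark
    if (mean(px_s) <= 0.05) {
      stop("probe not found: no bright region in frame", call. = FALSE)
    }
    mask <- matrix(TRUE, nrow(px), ncol(px))
  } else {
    thr <- tryCatch(EBImage::otsu(EBImage::Image(px_s), range = c(0, 1)),
                    error = function(e) NA_real_)
    if (is.na(thr) || !any(px_s > thr)) {
      stop("probe not found: no bright region in frame", call. = FALSE)
    }
    mask <- px_s > thr
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) < min_area_fraction * length(px)) {
    stop("probe not found: largest bright component below ",
         min_area_fraction * 100, "% of the raster", call. = FALSE)
  }
  best <- which.max(sizes)
  idx <- which(as.matrix(lab) == best, arr.ind = TRUE)
  # 0-based (x = column, y = row)
  cx <- mean(idx[, 2]) - 1
  cy <- mean(idx[, 1]) - 1
  n <- nrow(px)
  # equivalent radius, capped at the raster's inscribed circle
  r <- min(sqrt(nrow(idx) / pi), n / 2)
  x0 <- max(0L, as.integer(round(cx - r)))
  y0 <- max(0L, as.integer(round(cy - r)))
  x1 <- min(n, as.integer(round(cx + r)) + 1L)
  y1 <- min(n, as.integer(round(cy + r)) + 1L)
  structure(
    list(center = c(x = cx, y = cy), radius = r,
         bounding_square = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)),
    class = "probe_region"
  )
}

#' @export
print.probe_region <- function(x, ...) {
  cat(sprintf("<probe_region> center (%.1f, %.1f), radius %.1f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Resample a frame to a reference pixel pitch
#'
#' Bilinear resampling by `src_pitch / ref_pitch`. In the default
#' `printed_factor` mode the factor is rounded to one decimal, matching the
#' deployed convention of resizing 1.24 um/px frames by 1.6x to the
#' 0.78 um/px reference sampling; `printed_factor = FALSE` uses the exact
#' ratio. Output dimensions are `round(input * factor)`.
#'
#' @param frame An `hrme_frame`.
#' @param src_pitch,ref_pitch Source and reference pitches in um/px (> 0).
#' @param printed_factor Round the factor to one decimal (default `TRUE`).
#' @return The resampled `hrme_frame`; its params record the new pitch.
#' @export
resample_to_reference <- function(frame,
                                  src_pitch = frame$params$pixel_pitch,
                                  ref_pitch,
                                  printed_factor = TRUE) {
  stopifnot(inherits(frame, "hrme_frame"))
  if (src_pitch <= 0 || ref_pitch <= 0) {
    stop("pitches must be positive", call. = FALSE)
  }
  factor <- resize_factor(src_pitch, ref_pitch, printed_factor)
  if (factor == 1) return(frame)
  n <- nrow(frame$pixels)
  m <- as.integer(round(n * factor))
  res <- EBImage::resize(EBImage::Image(frame$pixels), w = m, h = m,
                         filter = "bilinear")
  frame$pixels <- pmin(pmax(as.matrix(res), 0), 1)
  frame$params$pixel_pitch <- src_pitch / factor
  frame
}

#' @rdname resample_to_reference
#' @return `resize_factor`: the numeric resampling factor.
#' @export
resize_factor <- function(src_pitch, ref_pitch, printed_factor = TRUE) {
  if (src_pitch <= 0 || ref_pitch <= 0) {
    stop("pitches must be positive", call. = FALSE)
  }
  f <- src_pitch / ref_pitch
  if (printed_factor) round(f, 1) else f
}

#' Split a probe crop into four quadrants
#'
#' Crops the probe's bounding square and splits it at its midpoint into four
#' sub-rasters in fixed order: top-left, top-right, bottom-left,
#' bottom-right. For an odd side the first row/column block gets the extra
#' pixel (floor split), so the four quadrants always tile the crop exactly.
#'
#' @param frame An `hrme_frame`.
#' @param region A `probe_region` from [detect_probe_region()]; must lie
#'   within the raster.
#' @return An object of class `quadrant_set`: list of 4 matrices, the pixel
#'   pitch, and provenance (region and crop size).
#' @export
split_quadrants <- function(frame, region) {
  stopifnot(inherits(frame, "hrme_frame"), inherits(region, "probe_region"))
  b <- region$bounding_square
  n <- nrow(frame$pixels)
  if (b["x0"] < 0 || b["y0"] < 0 || b["x1"] > n || b["y1"] > n ||
      b["x1"] <= b["x0"] || b["y1"] <= b["y0"]) {
    stop("probe region lies outside the raster", call. = FALSE)
  }
  rows <- (b["y0"] + 1L):b["y1"]
  cols <- (b["x0"] + 1L):b["x1"]
  crop <- frame$pixels[rows, cols, drop = FALSE]
  mr <- ceiling(nrow(crop) / 2)
  mc <- ceiling(ncol(crop) / 2)
  quads <- list(
    top_left = crop[1:mr, 1:mc, drop = FALSE],
    top_right = crop[1:mr, (mc + 1):ncol(crop), drop = FALSE],
    bottom_left = crop[(mr + 1):nrow(crop), 1:mc, drop = FALSE],
    bottom_right = crop[(mr + 1):nrow(crop), (mc + 1):ncol(crop), drop = FALSE]
  )
  structure(
    list(quadrants = quads, pixel_pitch = frame$params$pixel_pitch,
         provenance = list(bounding_square = b, crop_dim = dim(crop))),
    class = "quadrant_set"
  )
}

#' Baseline morphometry classifier weights
#'
#' Configuration constants of the baseline per-quadrant scorer: the nuclear
#' segmentation threshold (normalized intensity — fixed, not adaptive, so
#' that contrast changes genuinely move the features), and the logistic
#' weights on the morphometry summary. These are design constants, not
#' trained parameters; the baseline scorer is a stand-in for a learned
#' classifier and makes no claim of clinical accuracy.
#'
#' @param segmentation_threshold Normalized intensity above which pixels are
#'   counted as nuclear signal.
#' @param intercept,w_density,w_radius,w_area_fraction,w_contrast Logistic
#'   coefficients; the linear predictor is
#'   `intercept + w_density * density/1000 + w_radius * mean_radius/10 +
#'    w_area_fraction * area_fraction + w_contrast * (fg/bg - 1)/5`.
#' @return A named list of weights.
#' @export
baseline_classifier_weights <- function(segmentation_threshold = 0.3,
                                        intercept = -3.0,
                                        w_density = 2.2,
                                        w_radius = 1.2,
                                        w_area_fraction = 9.0,
                                        w_contrast = 1.2) {
  list(segmentation_threshold = segmentation_threshold, intercept = intercept,
       w_density = w_density, w_radius = w_radius,
       w_area_fraction = w_area_fraction, w_contrast = w_contrast)
}

# nuclear morphometry of one quadrant: segmentation at a fixed threshold,
# connected components, per-component areas; pitch in um/px
quadrant_morphometry <- function(quadrant, pixel_pitch,
                                 threshold = 0.5) {
  stopifnot(is.matrix(quadrant), length(quadrant) > 0L)
  mask <- quadrant > threshold
  area_mm2 <- length(quadrant) * pixel_pitch^2 / 1e6
  if (!any(mask)) {
    return(list(count = 0L, density = 0, mean_area_um2 = 0, sd_area_um2 = 0,
                mean_radius_um = 0, area_fraction = 0, intensity_ratio = 1,
                low_information = TRUE))
  }
  lab <- EBImage::bwlabel(mask)
  areas_px <- tabulate(as.integer(lab))
  areas_px <- areas_px[areas_px > 0]
  areas_um2 <- areas_px * pixel_pitch^2
  fg <- mean(quadrant[mask])
  bg <- if (all(mask)) fg else mean(quadrant[!mask])
  list(
    count = length(areas_px),
    density = length(areas_px) / area_mm2,
    mean_area_um2 = mean(areas_um2),
    sd_area_um2 = if (length(areas_um2) > 1) stats::sd(areas_um2) else 0,
    mean_radius_um = mean(sqrt(areas_um2 / pi)),
    area_fraction = mean(mask),
    intensity_ratio = if (bg > 0) fg / bg else 1,
    low_information = stats::sd(as.numeric(quadrant)) == 0
  )
}

#' Baseline per-quadrant probability of high-grade disease
#'
#' A deterministic morphometry scorer standing in for a learned quadrant
#' classifier: nuclear pixels are segmented at a fixed intensity threshold,
#' connected components give nucleus count density, mean equivalent radius
#' and nuclear area fraction, and a fixed logistic map of the weighted
#' feature sum yields a probability in \[0, 1\]. Denser, larger, brighter
#' nuclei — the morphologic signature of high-grade squamous lesions — raise
#' the score monotonically. A zero-variance quadrant is flagged
#' low-information and scored from the default (zero) features.
#'
#' @param quadrant A numeric matrix (one quadrant), or a `quadrant_set`
#'   element.
#' @param pixel_pitch Micrometers per pixel of the quadrant.
#' @param weights Weights from [baseline_classifier_weights()].
#' @return Probability in \[0, 1\]; attribute `low_information` flags
#'   degenerate input, attribute `features` carries the morphometry.
#' @export
baseline_quadrant_probability <- function(quadrant, pixel_pitch = 0.78,
                                          weights = baseline_classifier_weights()) {
  mo <- quadrant_morphometry(quadrant, pixel_pitch,
                             weights$segmentation_threshold)
  lp <- weights$intercept +
    weights$w_density * mo$density / 1000 +
    weights$w_radius * mo$mean_radius_um / 10 +
    weights$w_area_fraction * mo$area_fraction +
    weights$w_contrast * (mo$intensity_ratio - 1) / 5
  p <- stats::plogis(lp)
  attr(p, "low_information") <- mo$low_information
  attr(p, "features") <- mo
  p
}

#' Aggregate quadrant probabilities into a site score
#'
#' The site score is the arithmetic mean of the four quadrant probabilities;
#' the positivity call applies the cutoff via [call_site()]. Any classifier
#' can be plugged in; it must return a single value in \[0, 1\] per quadrant
#' or a contract-violation error is raised.
#'
#' @param quadrants A `quadrant_set` from [split_quadrants()].
#' @param classifier Function `(quadrant_matrix, pixel_pitch) -> probability`.
#' @param cutoff Positivity cutoff (default 0.4).
#' @param site_id Optional identifier carried into the result.
#' @return An object of class `site_score` with fields `site_id`,
#'   `quadrant_probabilities`, `score`, `cutoff` and `call`.
#' @export
score_site <- function(quadrants,
                       classifier = baseline_quadrant_probability,
                       cutoff = 0.4,
                       site_id = NA_character_) {
  stopifnot(inherits(quadrants, "quadrant_set"))
  probs <- vapply(quadrants$quadrants, function(q) {
    p <- as.numeric(classifier(q, quadrants$pixel_pitch))
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("classifier contract violation: output must be one value in [0, 1]",
           call. = FALSE)
    }
    p
  }, numeric(1))
  sc <- mean(probs)
  structure(
    list(site_id = site_id, quadrant_probabilities = probs, score = sc,
         cutoff = cutoff, call = call_site(sc, cutoff)),
    class = "site_score"
  )
}

#' @export
print.site_score <- function(x, ...) {
  cat(sprintf("<site_score> %s: score %.3f (%s at cutoff %.2f)\n",
              x$site_id, x$score, x$call, x$cutoff))
  invisible(x)
}

#' Positivity call from a site score
#'
#' A site is called positive iff its score is at or above the cutoff
#' (inclusive comparison; the deployed cutoff was 0.4, and the reference
#' example scores 0.08 / 0.67 / 0.71 are unaffected by tie handling).
#'
#' @param score Site score in \[0, 1\].
#' @param cutoff Positivity cutoff in \[0, 1\].
#' @return `"positive"` or `"negative"` (vectorized over `score`).
#' @export
call_site <- function(score, cutoff = 0.4) {
  if (any(score < 0 | score > 1) || cutoff < 0 || cutoff > 1) {
    stop("score and cutoff must lie in [0, 1]", call. = FALSE)
  }
  ifelse(score >= cutoff, "positive", "negative")
}

#' Automated image-quality assessment
#'
#' A computational proxy for the expert review rule that discards an image
#' when more than half the field of view is blurry or out of contact:
#' `contact_fraction` is the fraction of in-region pixels above a contact
#' intensity threshold (out-of-contact areas are dark), `sharp_fraction` is
#' the fraction of in-region tiles whose gradient energy exceeds a focus
#' threshold, and the image fails iff
#' `1 - min(contact_fraction, sharp_fraction) > criterion` (strict, so an
#' exactly half-degraded image still passes). The thresholds are stated
#' configuration defaults, not a validated replication of expert review.
#'
#' @param frame An `hrme_frame`.
#' @param region A `probe_region`.
#' @param criterion Degraded-fraction threshold (default 0.5).
#' @param contact_threshold Normalized intensity above which a pixel counts
#'   as in tissue contact.
#' @param focus_threshold Minimum per-tile mean squared finite-difference
#'   gradient for the tile to count as sharp.
#' @param tile Tile side in pixels for the focus map.
#' @return An object of class `qc_result` with fields `contact_fraction`,
#'   `sharp_fraction`, `pass` and `criterion`.
#' @export
assess_quality <- function(frame, region, criterion = 0.5,
                           contact_threshold = 0.1,
                           focus_threshold = 1e-4,
                           tile = 8L) {
  stopifnot(inherits(frame, "hrme_frame"), inherits(region, "probe_region"))
  n <- nrow(frame$pixels)
  idx0 <- seq_len(n) - 1
  x <- matrix(idx0, n, n, byrow = TRUE)
  y <- matrix(idx0, n, n)
  inreg <- (x - region$center["x"])^2 + (y - region$center["y"])^2 <=
    region$radius^2
  px <- frame$pixels
  contact <- mean(px[inreg] > contact_threshold)
  # tile-wise gradient energy over the bounding square
  b <- region$bounding_square
  crop <- px[(b["y0"] + 1L):b["y1"], (b["x0"] + 1L):b["x1"], drop = FALSE]
  gx <- crop[, -1, drop = FALSE] - crop[, -ncol(crop), drop = FALSE]
  gy <- crop[-1, , drop = FALSE] - crop[-nrow(crop), , drop = FALSE]
  energy <- matrix(0, nrow(crop), ncol(crop))
  energy[, -1] <- gx^2
  energy[-1, ] <- energy[-1, ] + gy^2
  rb <- (seq_len(nrow(crop)) - 1L) %/% tile
  cb <- (seq_len(ncol(crop)) - 1L) %/% tile
  tile_energy <- tapply(as.numeric(energy),
                        list(rb[row(energy)], cb[col(energy)]), mean)
  sharp <- mean(tile_energy > focus_threshold, na.rm = TRUE)
  degraded <- 1 - min(contact, sharp)
  structure(
    list(contact_fraction = contact, sharp_fraction = sharp,
         pass = !(degraded > criterion), criterion = criterion),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> contact %.2f, sharp %.2f -> %s (criterion %.2f)\n",
              x$contact_fraction, x$sharp_fraction,
              if (x$pass) "pass" else "fail", x$criterion))
  invisible(x)
}
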