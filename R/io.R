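#' Read and write frames as TIFF / PNG
#'
#' Frames are held in memory as normalized floating-point intensities;
#' quantization happens only here. `write_frame_tiff()` writes a single
#' 16-bit grayscale TIFF, `write_sequence_tiff()` a multi-page TIFF (one
#' page per frame), and `write_frame_png()` an 8-bit PNG export.
#' `read_frame_tiff()` reads a page back into an `hrme_frame`, attaching the
#' supplied acquisition parameters (TIFF tags do not carry them).
#'
#' @param frame An `hrme_frame`.
#' @param seq An `hrme_sequence`.
#' @param path File path.
#' @param params [acquisition_params()] to attach on read.
#' @param page 1-based page index for multi-page files.
#' @param gamma_encoded Flag to attach on read.
#' @return Writers return `path` invisibly; readers an `hrme_frame`.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "hrme_frame"))
  tiff::writeTIFF(frame$pixels, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
write_sequence_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "hrme_sequence"))
  tiff::writeTIFF(lapply(seq$frames, `[[`, "pixels"), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "hrme_frame"))
  png::writePNG(frame$pixels, path)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path, params, page = 1L, gamma_encoded = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (page < 1L || page > length(pages)) {
    stop("page index out of range", call. = FALSE)
  }
  px <- pages[[page]]
  if (length(dim(px)) == 3L) px <- px[, , 1]
  new_frame(pmin(pmax(px, 0), 1), params, timestamp = 0,
            gamma_encoded = gamma_encoded)
}

#' @rdname write_frame_tiff
#' @export
read_sequence_tiff <- function(path, params, gamma_encoded = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  period <- 1000 / params$frame_rate
  frames <- lapply(seq_along(pages), function(i) {
    px <- pages[[i]]
    if (length(dim(px)) == 3L) px <- px[, , 1]
    new_frame(pmin(pmax(px, 0), 1), params, timestamp = (i - 1) * period,
              gamma_encoded = gamma_encoded)
  })
  new_sequence(frames, selected_index = length(frames))
}
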