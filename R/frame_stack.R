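#' Construct a frame stack
#'
#' A frame stack is a time-ordered stack of 2-D grayscale intensity frames
#' with physical calibration: the in-memory representation of a contrast-mode
#' clip. Axial index increases with depth (away from the probe).
#'
#' @param frames Numeric 3-D array, time x axial x lateral, linear intensity.
#' @param meta An [acquisition_meta()] object.
#' @return An object of class `frame_stack` with elements `frames` and `meta`.
#' @export
frame_stack <- function(frames, meta) {
  validate_meta(meta)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (time x axial x lateral)")
  }
  if (dim(frames)[1] < 1L) stop("frame stack needs at least one frame")
  if (any(!is.finite(frames))) stop("frame stack contains non-finite values")
  structure(list(frames = frames, meta = meta), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d (axial) x %d (lateral) px\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %.3g s at %g Hz; pitch %g x %g mm\n",
              (d[1] - 1) / x$meta$frame_rate, x$meta$frame_rate,
              x$meta$pixel_pitch_axial, x$meta$pixel_pitch_lateral))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[1]

#' Write a frame stack as multi-frame TIFF plus metadata sidecar
#'
#' Frames are stored as 32-bit TIFF pages in acquisition order, rescaled to
#' the unit interval; the normalization constant and the calibration go to a
#' YAML sidecar (`<path>.meta.yaml`) with keys `pixel_pitch_axial_mm`,
#' `pixel_pitch_lateral_mm`, `frame_rate_hz`, `transmit_frequency_mhz`,
#' `sound_speed_mm_us`, `intensity_scale`.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path.
#' @return Invisibly, the paths written (tiff, sidecar).
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  lo <- min(stack$frames)
  if (lo < 0) stop("frame stack intensities must be nonnegative for TIFF export")
  scale <- max(stack$frames)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) stack$frames[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- paste0(path, ".meta.yaml")
  m <- stack$meta
  yaml::write_yaml(list(pixel_pitch_axial_mm = m$pixel_pitch_axial,
                        pixel_pitch_lateral_mm = m$pixel_pitch_lateral,
                        frame_rate_hz = m$frame_rate,
                        transmit_frequency_mhz = m$transmit_frequency,
                        sound_speed_mm_us = m$sound_speed,
                        intensity_scale = scale), side)
  invisible(c(tiff = path, sidecar = side))
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path; the sidecar `<path>.meta.yaml` must sit next to it.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  side <- paste0(path, ".meta.yaml")
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  s <- yaml::read_yaml(side)
  meta <- acquisition_meta(pixel_pitch_axial = s$pixel_pitch_axial_mm,
                           pixel_pitch_lateral = s$pixel_pitch_lateral_mm,
                           frame_rate = s$frame_rate_hz,
                           transmit_frequency = s$transmit_frequency_mhz,
                           sound_speed = s$sound_speed_mm_us)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (is.null(s$intensity_scale)) 1 else s$intensity_scale
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  frame_stack(frames, meta)
}
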