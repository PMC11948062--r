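#' Acquisition metadata for a CEUS clip
#'
#' Bundles the physical calibration of a contrast-mode acquisition: pixel
#' pitches, frame rate, transmit frequency and assumed sound speed. The
#' wavelength (`sound_speed / transmit_frequency`, in mm) is derived here and
#' used downstream, most importantly by the track-linking gate (2 lambda).
#'
#' Defaults mirror a transfontanellar neonatal acquisition: 14 Hz frame rate,
#' 4 MHz transmit frequency, c = 1.54 mm/us (lambda = 0.385 mm) and a 0.1 mm
#' pixel pitch, so that a 10x upsampled map has 10 um pixels.
#'
#' @param pixel_pitch_axial Axial pixel pitch in mm/px.
#' @param pixel_pitch_lateral Lateral pixel pitch in mm/px.
#' @param frame_rate Frame rate in Hz.
#' @param transmit_frequency Transmit frequency in MHz.
#' @param sound_speed Speed of sound in mm/us.
#' @return An object of class `acq_meta`: a list with the five calibration
#'   fields plus the derived `wavelength` (mm).
#' @examples
#' meta <- acquisition_meta()
#' meta$wavelength  # 0.385 mm at 4 MHz
#' @export
acquisition_meta <- function(pixel_pitch_axial = 0.1,
                             pixel_pitch_lateral = 0.1,
                             frame_rate = 14,
                             transmit_frequency = 4,
                             sound_speed = 1.54) {
  vals <- c(pixel_pitch_axial = pixel_pitch_axial,
            pixel_pitch_lateral = pixel_pitch_lateral,
            frame_rate = frame_rate,
            transmit_frequency = transmit_frequency,
            sound_speed = sound_speed)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition metadata fields must be finite and strictly positive")
  }
  ## c in mm/us, f in MHz: lambda [mm] = c/f
  meta <- list(pixel_pitch_axial = pixel_pitch_axial,
               pixel_pitch_lateral = pixel_pitch_lateral,
               frame_rate = frame_rate,
               transmit_frequency = transmit_frequency,
               sound_speed = sound_speed,
               wavelength = sound_speed / transmit_frequency)
  class(meta) <- "acq_meta"
  meta
}

#' @export
print.acq_meta <- function(x, ...) {
  cat("CEUS acquisition metadata\n")
  cat(sprintf("  pixel pitch (axial x lateral): %g x %g mm\n",
              x$pixel_pitch_axial, x$pixel_pitch_lateral))
  cat(sprintf("  frame rate: %g Hz\n", x$frame_rate))
  cat(sprintf("  transmit frequency: %g MHz (sound speed %g mm/us)\n",
              x$transmit_frequency, x$sound_speed))
  cat(sprintf("  wavelength: %g mm\n", x$wavelength))
  invisible(x)
}

validate_meta <- function(meta) {
  if (!inherits(meta, "acq_meta")) stop("`meta` must be an `acq_meta` object")
  rel <- abs(meta$wavelength - meta$sound_speed / meta$transmit_frequency) /
    meta$wavelength
  if (rel > 1e-9) stop("wavelength inconsistent with sound_speed/transmit_frequency")
  invisible(meta)
}
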