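#' Flow direction of a track relative to the probe
#'
#' Axial index increases with depth, so a negative net axial displacement
#' (last minus first point) means the bubble approached the probe.
#'
#' @param points n x 2 matrix of track positions (axial_mm, lateral_mm).
#' @return `"upward"` (toward the probe), `"downward"` (away), or
#'   `"neutral"` (zero net axial displacement or single-point track).
#' @export
classify_direction <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 2) return("neutral")
  net <- points[nrow(points), 1] - points[1, 1]
  if (net < 0) "upward" else if (net > 0) "downward" else "neutral"
}

#' Accumulate tracks into super-resolved ULM maps
#'
#' Every track is resampled along its polyline at the fine-grid pitch
#' (acquisition pitch / `factor`) and each resampled point increments the
#' fine pixel containing it. Three grids are built:
#' \describe{
#'   \item{density}{count of resampled track points per fine pixel;}
#'   \item{directivity}{signed count: +1 per point of an upward (toward
#'     probe) track, -1 per downward point, 0 for neutral tracks;}
#'   \item{velocity}{mean over contributing tracks of the track-mean velocity
#'     (mm/s), 0 where no track with defined velocity passes.}
#' }
#' With the default 0.1 mm pitch and `factor = 10` the fine pixel is 10 um.
#' A point at position `x` goes to fine pixel `floor(x / fine_pitch)`
#' (0-based); boundary points go to the higher index. Accumulation is
#' order-independent.
#'
#' @param tracks A [link_tracks()] result (empty allowed).
#' @param meta An [acquisition_meta()]; taken from `tracks` if `NULL`.
#' @param factor Integer upsampling factor (default 10).
#' @param extent Optional c(axial, lateral) extent in mm of the mapped field;
#'   defaults to the track bounding box rounded up to whole coarse pixels.
#' @return An object of class `ulm_maps`: list with `density`, `directivity`,
#'   `velocity` matrices, `fine_pitch` (c(axial, lateral) mm),
#'   `upsampling_factor`, `meta`.
#' @export
accumulate_maps <- function(tracks, meta = NULL, factor = 10L, extent = NULL) {
  if (is.null(meta)) meta <- attr(tracks, "meta")
  validate_meta(meta)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1")
  fp_ax <- meta$pixel_pitch_axial / factor
  fp_lat <- meta$pixel_pitch_lateral / factor
  df <- as.data.frame(tracks)
  if (is.null(extent)) {
    if (nrow(df) == 0) {
      extent <- c(meta$pixel_pitch_axial, meta$pixel_pitch_lateral)
    } else {
      extent <- c(ceiling(max(df$axial_mm) / meta$pixel_pitch_axial + 1e-12) *
                    meta$pixel_pitch_axial,
                  ceiling(max(df$lateral_mm) / meta$pixel_pitch_lateral + 1e-12) *
                    meta$pixel_pitch_lateral)
    }
  }
  n_ax <- max(1L, as.integer(ceiling(extent[1] / fp_ax)) + 1L)
  n_lat <- max(1L, as.integer(ceiling(extent[2] / fp_lat)) + 1L)
  density <- matrix(0, n_ax, n_lat)
  directivity <- matrix(0, n_ax, n_lat)
  vel_sum <- matrix(0, n_ax, n_lat)
  vel_n <- matrix(0, n_ax, n_lat)
  step <- min(fp_ax, fp_lat)
  for (tr in track_list(tracks)) {
    pts <- interpolate_track(tr, step)
    ia <- floor(pts[, 1] / fp_ax) + 1L
    il <- floor(pts[, 2] / fp_lat) + 1L
    ok <- ia >= 1L & ia <= n_ax & il >= 1L & il <= n_lat
    idx <- cbind(ia[ok], il[ok])
    if (!nrow(idx)) next
    dir <- classify_direction(tr)
    sgn <- switch(dir, upward = 1, downward = -1, neutral = 0)
    ## sparse tabulated increments keep accumulation order-independent
    tb <- table((idx[, 2] - 1) * n_ax + idx[, 1])
    pos <- as.integer(names(tb))
    cnt <- as.numeric(tb)
    density[pos] <- density[pos] + cnt
    directivity[pos] <- directivity[pos] + sgn * cnt
    if (nrow(tr) >= 2) {
      v <- track_velocity(tr, meta$frame_rate)
      vel_sum[pos] <- vel_sum[pos] + v * cnt
      vel_n[pos] <- vel_n[pos] + cnt
    }
  }
  velocity <- ifelse(vel_n > 0, vel_sum / pmax(vel_n, 1), 0)
  structure(list(density = density, directivity = directivity,
                 velocity = velocity,
                 fine_pitch = c(axial = fp_ax, lateral = fp_lat),
                 upsampling_factor = factor, meta = meta),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("ulm_maps: %d x %d fine grid, pitch %g x %g mm (%gx upsampled)\n",
              nrow(x$density), ncol(x$density),
              x$fine_pitch[1], x$fine_pitch[2], x$upsampling_factor))
  cat(sprintf("  total accumulated points: %g; velocity range %.2f..%.2f mm/s\n",
              sum(x$density), min(x$velocity), max(x$velocity)))
  invisible(x)
}

#' Render ULM maps
#'
#' Density is shown log-compressed (hot colormap); directivity with the
#' conventional encoding, red for flow toward the probe (upward) and blue
#' away from it. Stored grids stay raw counts; this is presentation only.
#'
#' @param x A `ulm_maps` object.
#' @param which `"density"`, `"directivity"` or `"velocity"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.ulm_maps <- function(x, which = c("density", "directivity", "velocity"),
                          ...) {
  which <- match.arg(which)
  ax <- (seq_len(nrow(x$density)) - 0.5) * x$fine_pitch[1]
  lat <- (seq_len(ncol(x$density)) - 0.5) * x$fine_pitch[2]
  if (which == "density") {
    z <- log1p(x$density)
    col <- grDevices::hcl.colors(64, "Inferno")
    graphics::image(lat, rev(ax), t(z[rev(seq_along(ax)), ]), col = col,
                    xlab = "lateral (mm)", ylab = "axial (mm)",
                    main = "ULM density (log)", useRaster = TRUE, ...)
  } else if (which == "directivity") {
    z <- x$directivity
    m <- max(abs(z), 1)
    col <- grDevices::colorRampPalette(c("blue", "black", "red"))(65)
    graphics::image(lat, rev(ax), t(z[rev(seq_along(ax)), ]), col = col,
                    zlim = c(-m, m), xlab = "lateral (mm)",
                    ylab = "axial (mm)", main = "ULM directivity",
                    useRaster = TRUE, ...)
  } else {
    col <- grDevices::hcl.colors(64, "Viridis")
    graphics::image(lat, rev(ax), t(x$velocity[rev(seq_along(ax)), ]),
                    col = col, xlab = "lateral (mm)", ylab = "axial (mm)",
                    main = "ULM velocity (mm/s)", useRaster = TRUE, ...)
  }
  invisible(x)
}

#' Write ULM maps as TIFF files with sidecars
#'
#' Each grid goes to `<prefix>_<name>.tif` (32-bit, normalized, scale in the
#' sidecar) with `<file>.meta.yaml` recording fine pitch and extent.
#'
#' @param maps A `ulm_maps` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "ulm_maps"))
  files <- character(0)
  for (name in c("density", "directivity", "velocity")) {
    z <- maps[[name]]
    lo <- min(z); hi <- max(z)
    scale <- max(abs(lo), abs(hi), 1e-300)
    path <- sprintf("%s_%s.tif", prefix, name)
    tiff::writeTIFF((z / scale + 1) / 2, path, bits.per.sample = 32L)
    yaml::write_yaml(list(map = name, intensity_scale = scale,
                          encoding = "value = (2*stored - 1) * intensity_scale",
                          fine_pitch_axial_mm = as.numeric(maps$fine_pitch[1]),
                          fine_pitch_lateral_mm = as.numeric(maps$fine_pitch[2]),
                          extent_axial_mm = nrow(z) * as.numeric(maps$fine_pitch[1]),
                          extent_lateral_mm = ncol(z) * as.numeric(maps$fine_pitch[2]),
                          upsampling_factor = maps$upsampling_factor),
                    paste0(path, ".meta.yaml"))
    files <- c(files, path)
  }
  invisible(files)
}
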