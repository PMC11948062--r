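#' Build a synthetic vessel phantom
#'
#' Defines the geometry a synthetic microbubble flow runs through: one or
#' more vessel centerlines (polylines in mm), each with a radius, a mean flow
#' speed and a flow direction along the polyline. It stands in for the
#' microvasculature a clinical clip would image, so that localization,
#' tracking and mapping can be validated against known geometry and speeds.
#'
#' @param segments List of segments. Each segment is a list with:
#'   \describe{
#'     \item{centerline}{n x 2 matrix of (axial_mm, lateral_mm) polyline
#'       vertices, n >= 2.}
#'     \item{radius}{Vessel radius in mm, > 0.}
#'     \item{speed}{Mean flow speed in mm/s, >= 0.}
#'     \item{direction}{+1 to flow along vertex order, -1 reversed
#'       (default +1).}
#'   }
#' @param field_of_view Numeric length-2, (axial extent, lateral extent) in
#'   mm. All centerline points must lie in `[0, extent]` on both axes.
#' @return An object of class `vessel_phantom`.
#' @examples
#' ph <- vessel_phantom(
#'   segments = list(list(centerline = rbind(c(10, 5), c(10, 25)),
#'                        radius = 0.05, speed = 4)),
#'   field_of_view = c(20, 30))
#' @export
vessel_phantom <- function(segments, field_of_view) {
  if (length(segments) < 1L) stop("phantom needs at least one segment")
  if (length(field_of_view) != 2L || any(field_of_view <= 0)) {
    stop("`field_of_view` must be two positive extents (axial, lateral) in mm")
  }
  segments <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    cl <- as.matrix(s$centerline)
    if (ncol(cl) != 2L || nrow(cl) < 2L) {
      stop(sprintf("segment %d: centerline must be an n x 2 matrix, n >= 2", i))
    }
    if (any(cl[, 1] < 0 | cl[, 1] > field_of_view[1] |
            cl[, 2] < 0 | cl[, 2] > field_of_view[2])) {
      stop(sprintf("segment %d: centerline leaves the field of view", i))
    }
    if (is.null(s$radius) || s$radius <= 0) {
      stop(sprintf("segment %d: radius must be > 0", i))
    }
    if (is.null(s$speed) || s$speed < 0) {
      stop(sprintf("segment %d: speed must be >= 0", i))
    }
    dir <- if (is.null(s$direction)) 1L else as.integer(sign(s$direction))
    if (dir == 0L) stop(sprintf("segment %d: direction must be +1 or -1", i))
    if (dir < 0L) cl <- cl[rev(seq_len(nrow(cl))), , drop = FALSE]
    steps <- sqrt(rowSums((cl[-1, , drop = FALSE] -
                           cl[-nrow(cl), , drop = FALSE])^2))
    if (any(steps == 0)) {
      stop(sprintf("segment %d: centerline has duplicated consecutive points", i))
    }
    list(centerline = cl, radius = s$radius, speed = s$speed,
         arc = c(0, cumsum(steps)), length = sum(steps))
  })
  structure(list(segments = segments, field_of_view = field_of_view),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("vessel_phantom: %d segment(s), field of view %g x %g mm\n",
              length(x$segments), x$field_of_view[1], x$field_of_view[2]))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    cat(sprintf("  [%d] length %.2f mm, radius %g mm, speed %g mm/s\n",
                i, s$length, s$radius, s$speed))
  }
  invisible(x)
}

## position + unit tangent on a polyline at arc length a (clamped to range)
polyline_point <- function(cl, arc, a) {
  a <- min(max(a, 0), arc[length(arc)])
  j <- findInterval(a, arc, rightmost.closed = TRUE)
  j <- min(max(j, 1L), nrow(cl) - 1L)
  seg <- cl[j + 1, ] - cl[j, ]
  len <- sqrt(sum(seg^2))
  t <- (a - arc[j]) / len
  list(pos = cl[j, ] + t * seg, tangent = seg / len)
}

#' Simulate microbubble transits through a vessel phantom
#'
#' Each bubble enters a randomly chosen segment (probability proportional to
#' segment length) at a random arc-length offset and a random arrival frame,
#' then advances along the centerline by `speed / frame_rate` mm per frame
#' until it exits the segment, its lifetime ends, or the clip ends. A
#' per-bubble perpendicular streamline offset, uniform within the vessel
#' radius, models the finite vessel width; the bubble keeps this offset over
#' its transit (laminar-flow streamline), so the imposed along-vessel speed
#' is exactly preserved.
#'
#' @param phantom A [vessel_phantom()].
#' @param meta An [acquisition_meta()].
#' @param n_bubbles Number of bubble transits to draw (>= 1).
#' @param duration Clip duration in s (`duration * frame_rate >= 2`).
#' @param arrival_profile Either `"uniform"` (default) or a list
#'   `list(A, mu, sigma, t0)` giving lognormal bolus weighting of arrival
#'   times (the model of [simulate_tic()]).
#' @param max_lifetime_frames Optional cap on frames a bubble persists
#'   (models destruction / out-of-plane loss); `Inf` to disable.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `phantom_truth`: a list with `trajectories`
#'   (data.frame: bubble_id, frame, axial_mm, lateral_mm, segment_id,
#'   speed_mm_s), `n_frames`, and `seed`. Frame indices are 0-based.
#' @export
simulate_bubbles <- function(phantom, meta, n_bubbles, duration,
                             arrival_profile = "uniform",
                             max_lifetime_frames = Inf, seed = 1L) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  validate_meta(meta)
  if (n_bubbles < 1L) stop("`n_bubbles` must be >= 1")
  nf <- floor(duration * meta$frame_rate)
  if (nf < 2L) stop("duration must cover at least 2 frames")
  set_local_seed(seed)

  seg_len <- vapply(phantom$segments, `[[`, numeric(1), "length")
  seg_id <- sample.int(length(phantom$segments), n_bubbles, replace = TRUE,
                       prob = seg_len)
  entry_frame <- draw_arrival_frames(n_bubbles, nf, meta$frame_rate,
                                     arrival_profile)
  entry_arc <- stats::runif(n_bubbles) * seg_len[seg_id]
  out <- vector("list", n_bubbles)
  for (b in seq_len(n_bubbles)) {
    s <- phantom$segments[[seg_id[b]]]
    ## constant perpendicular streamline offset within the tube
    off <- stats::runif(1, -s$radius, s$radius)
    step <- s$speed / meta$frame_rate
    n_max <- nf - entry_frame[b]
    if (is.finite(max_lifetime_frames)) n_max <- min(n_max, max_lifetime_frames)
    if (step > 0) {
      n_step <- min(n_max, floor((s$length - entry_arc[b]) / step) + 1L)
    } else {
      n_step <- n_max
    }
    if (n_step < 1L) next
    arcs <- entry_arc[b] + step * (seq_len(n_step) - 1L)
    pts <- t(vapply(arcs, function(a) {
      pp <- polyline_point(s$centerline, s$arc, a)
      nrm <- c(-pp$tangent[2], pp$tangent[1])  # perpendicular in (ax, lat)
      pp$pos + off * nrm
    }, numeric(2)))
    inside <- pts[, 1] >= 0 & pts[, 1] <= phantom$field_of_view[1] &
      pts[, 2] >= 0 & pts[, 2] <= phantom$field_of_view[2]
    if (any(!inside)) {  # truncate at first exit, do not wrap
      first_out <- which(!inside)[1]
      if (first_out == 1L) next
      pts <- pts[seq_len(first_out - 1L), , drop = FALSE]
    }
    out[[b]] <- data.frame(bubble_id = b,
                           frame = entry_frame[b] + seq_len(nrow(pts)) - 1L,
                           axial_mm = pts[, 1], lateral_mm = pts[, 2],
                           segment_id = seg_id[b], speed_mm_s = s$speed)
  }
  traj <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(traj)) {
    traj <- data.frame(bubble_id = integer(0), frame = integer(0),
                       axial_mm = numeric(0), lateral_mm = numeric(0),
                       segment_id = integer(0), speed_mm_s = numeric(0))
  }
  rownames(traj) <- NULL
  structure(list(trajectories = traj, n_frames = nf, phantom = phantom,
                 seed = seed),
            class = "phantom_truth")
}

draw_arrival_frames <- function(n, nf, frame_rate, profile) {
  if (identical(profile, "uniform")) {
    return(sample.int(nf, n, replace = TRUE) - 1L)
  }
  if (!is.list(profile)) stop("`arrival_profile` must be \"uniform\" or a list")
  t <- (seq_len(nf) - 1L) / frame_rate
  w <- lognormal_bolus(t, A = profile$A %||% 1, mu = profile$mu,
                       sigma = profile$sigma, t0 = profile$t0 %||% 0,
                       baseline = 0)
  if (sum(w) <= 0) stop("arrival profile has zero mass over the clip")
  sample.int(nf, n, replace = TRUE, prob = w) - 1L
}

#' @export
print.phantom_truth <- function(x, ...) {
  tr <- x$trajectories
  cat(sprintf("phantom_truth: %d bubble track(s), %d localizations, %d frames\n",
              length(unique(tr$bubble_id)), nrow(tr), x$n_frames))
  invisible(x)
}

#' Render a phantom truth into a synthetic CEUS clip
#'
#' Each frame is the sum of (i) low-rank quasi-static tissue clutter -- a set
#' of `clutter_rank` fixed smooth spatial fields, each modulated by a slowly
#' varying temporal gain, (ii) one isotropic Gaussian point-spread blob per
#' bubble present in the frame, and (iii) white Gaussian noise. By default
#' the clutter dominates the bubble signal, as in vivo, so that detection is
#' only possible after clutter filtering.
#'
#' @param truth A [simulate_bubbles()] result.
#' @param meta An [acquisition_meta()].
#' @param psf_sigma Gaussian PSF sigma in mm; default `wavelength / 2.355`
#'   (diffraction-limited FWHM of one wavelength).
#' @param bubble_amplitude Peak intensity of one bubble (default 1).
#' @param clutter_amplitude Scale of the clutter field (default 50, i.e.
#'   clutter-dominated).
#' @param clutter_rank Number of spatial/temporal clutter components.
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param seed Integer seed for clutter and noise.
#' @return A [frame_stack()] of `truth$n_frames` frames covering the phantom
#'   field of view at the acquisition pixel pitch.
#' @export
render_movie <- function(truth, meta, psf_sigma = NULL,
                         bubble_amplitude = 1, clutter_amplitude = 50,
                         clutter_rank = 3, noise_sigma = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  validate_meta(meta)
  if (is.null(psf_sigma)) psf_sigma <- meta$wavelength / 2.355
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0")
  fov <- truth$phantom$field_of_view
  n_ax <- floor(fov[1] / meta$pixel_pitch_axial) + 1L
  n_lat <- floor(fov[2] / meta$pixel_pitch_lateral) + 1L
  nf <- truth$n_frames
  set_local_seed(seed)

  frames <- array(0, dim = c(nf, n_ax, n_lat))
  if (clutter_rank > 0 && clutter_amplitude > 0) {
    cl <- clutter_field(nf, n_ax, n_lat, clutter_rank, clutter_amplitude)
    for (i in seq_len(nf)) {
      frames[i, , ] <- cl$spatial %*% (cl$gain[i, ] * t(cl$lat))
    }
  }
  ## bubbles: truncated Gaussian footprint, +-4 sigma window
  tr <- truth$trajectories
  if (nrow(tr) > 0 && bubble_amplitude > 0) {
    hw_ax <- ceiling(4 * psf_sigma / meta$pixel_pitch_axial)
    hw_lat <- ceiling(4 * psf_sigma / meta$pixel_pitch_lateral)
    for (k in seq_len(nrow(tr))) {
      fi <- tr$frame[k] + 1L
      pa <- tr$axial_mm[k] / meta$pixel_pitch_axial      # 0-based px
      pl <- tr$lateral_mm[k] / meta$pixel_pitch_lateral
      ia <- max(1L, floor(pa) + 1L - hw_ax):min(n_ax, floor(pa) + 1L + hw_ax)
      il <- max(1L, floor(pl) + 1L - hw_lat):min(n_lat, floor(pl) + 1L + hw_lat)
      if (!length(ia) || !length(il)) next
      da <- ((ia - 1L) - pa) * meta$pixel_pitch_axial
      dl <- ((il - 1L) - pl) * meta$pixel_pitch_lateral
      blob <- bubble_amplitude *
        exp(-outer(da^2, dl^2, `+`) / (2 * psf_sigma^2))
      frames[fi, ia, il] <- frames[fi, ia, il] + blob
    }
  }
  if (noise_sigma > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sigma),
                             dim = dim(frames))
  }
  frame_stack(frames, meta)
}

## rank-r clutter: separable smooth spatial fields x slow temporal gains.
## First component is near-static (dominant tissue echo), higher ones drift
## as slow cosines with random phase.
clutter_field <- function(nf, n_ax, n_lat, rank, amplitude) {
  ax <- seq(0, 1, length.out = n_ax)
  lat <- seq(0, 1, length.out = n_lat)
  spatial <- matrix(0, n_ax, rank)
  latm <- matrix(0, n_lat, rank)
  for (r in seq_len(rank)) {
    f_ax <- stats::runif(1, 0.5, 1.5) * r
    f_lat <- stats::runif(1, 0.5, 1.5) * r
    spatial[, r] <- amplitude / r *
      (1.2 + cos(2 * pi * f_ax * ax + stats::runif(1, 0, 2 * pi)))
    latm[, r] <- 1.2 + cos(2 * pi * f_lat * lat + stats::runif(1, 0, 2 * pi))
  }
  t <- seq(0, 1, length.out = nf)
  gain <- matrix(0, nf, rank)
  gain[, 1] <- 1 + 0.02 * sin(2 * pi * t)      # quasi-static
  if (rank > 1) for (r in 2:rank) {
    gain[, r] <- 0.5 * (1 + 0.3 * cos(2 * pi * stats::runif(1, 0.5, 2) * t +
                                        stats::runif(1, 0, 2 * pi)))
  }
  list(spatial = spatial, lat = latm, gain = gain)
}

#' Write / read phantom ground truth as CSV
#'
#' Columns: bubble_id, frame, axial_mm, lateral_mm, segment_id, speed_mm_s.
#'
#' @param truth A `phantom_truth`.
#' @param path CSV path.
#' @return `write_phantom_truth` invisibly returns `path`;
#'   `read_phantom_truth` returns the trajectory data.frame.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  utils::write.csv(truth$trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom_truth
#' @export
read_phantom_truth <- function(path) {
  utils::read.csv(path)
}
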