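#' Mean velocity of a track
#'
#' Distance covered by the track divided by the time it takes to cover it:
#' cumulative path length over `(n_points - 1) / frame_rate` seconds, in
#' mm/s. Undefined (NA) for single-point tracks.
#'
#' @param points n x 2 track positions in mm.
#' @param frame_rate Frame rate in Hz.
#' @return Velocity in mm/s, or NA if `n < 2`.
#' @export
track_velocity <- function(points, frame_rate) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 2) return(NA_real_)
  path_length(points) / ((n - 1) / frame_rate)
}

path_length <- function(points) {
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

## interior turning angles in degrees, in [0, 180]; steps of zero length
## have no direction and are skipped (NA)
turning_angles <- function(points) {
  d <- diff(points)
  n <- nrow(d)
  if (n < 2) return(numeric(0))
  a <- d[-n, , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  dot <- a[, 1] * b[, 1] + a[, 2] * b[, 2]
  ang <- atan2(abs(cross), dot) * 180 / pi
  zero <- rowSums(a^2) == 0 | rowSums(b^2) == 0
  ang[zero] <- NA_real_
  ang
}

#' Dispersity of a track
#'
#' Number of direction changes exceeding `angle_threshold` degrees
#' (turning angle between consecutive displacement vectors), divided by the
#' number of points in the track; dimensionless in `[0, 1]`. Tracks with
#' fewer than 3 points return 0. Zero-length steps have undefined direction
#' and their interior angles are skipped.
#'
#' @param points n x 2 track positions in mm.
#' @param angle_threshold Direction-change threshold in degrees (default 20).
#' @return Dispersity (a.u.).
#' @export
dispersity <- function(points, angle_threshold = 20) {
  points <- rbind(points)
  if (nrow(points) < 3) return(0)
  ang <- turning_angles(points)
  sum(ang > angle_threshold, na.rm = TRUE) / nrow(points)
}

#' Tortuosity of a track
#'
#' Sum of the absolute interior turning angles (degrees) divided by the
#' Euclidean distance between the first and last point (mm): deg/mm. A
#' straight track has tortuosity 0. Undefined (NA) for a closed track
#' (first point equals last) and 0 for tracks with fewer than 3 points.
#'
#' @param points n x 2 track positions in mm.
#' @return Tortuosity in deg/mm, or NA for a closed track.
#' @export
tortuosity <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 3) return(0)
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (chord == 0) return(NA_real_)
  sum(turning_angles(points), na.rm = TRUE) / chord
}

#' Distance metric (path straightness ratio) of a track
#'
#' Cumulative distance traveled divided by the distance between the first
#' and last point; dimensionless, always >= 1, equal to 1 only for a
#' straight monotone track. Undefined (NA) for a closed track or a
#' single-point track.
#'
#' @param points n x 2 track positions in mm.
#' @return The ratio, or NA when undefined.
#' @export
distance_metric <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 2) return(NA_real_)
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (chord == 0) return(NA_real_)
  path_length(points) / chord
}

#' Per-track metric table for a track set
#'
#' Computes every per-track readout in one pass: number of points, duration,
#' path length, mean velocity, dispersity, tortuosity, distance metric and
#' flow direction. Metrics whose preconditions a track fails (velocity for
#' single-point tracks, tortuosity/DM for closed tracks) are NA for that
#' track and are excluded from that metric's distribution only.
#'
#' @param tracks A [link_tracks()] result or [read_tracks()] output.
#' @param meta An [acquisition_meta()]; taken from `tracks` if `NULL`.
#' @param angle_threshold Dispersity direction-change threshold in degrees.
#' @return data.frame with one row per track: `track_id`, `n_points`,
#'   `duration_s`, `path_length_mm`, `velocity_mm_s`, `dispersity`,
#'   `tortuosity_deg_mm`, `distance_metric`, `direction`.
#' @export
track_metrics <- function(tracks, meta = NULL, angle_threshold = 20) {
  if (is.null(meta)) meta <- attr(tracks, "meta")
  validate_meta(meta)
  tl <- track_list(tracks)
  if (!length(tl)) {
    return(data.frame(track_id = integer(0), n_points = integer(0),
                      duration_s = numeric(0), path_length_mm = numeric(0),
                      velocity_mm_s = numeric(0), dispersity = numeric(0),
                      tortuosity_deg_mm = numeric(0),
                      distance_metric = numeric(0), direction = character(0)))
  }
  rows <- lapply(names(tl), function(id) {
    p <- tl[[id]]
    n <- nrow(p)
    data.frame(track_id = as.integer(id), n_points = n,
               duration_s = (n - 1) / meta$frame_rate,
               path_length_mm = if (n >= 2) path_length(p) else 0,
               velocity_mm_s = track_velocity(p, meta$frame_rate),
               dispersity = dispersity(p, angle_threshold),
               tortuosity_deg_mm = tortuosity(p),
               distance_metric = distance_metric(p),
               direction = classify_direction(p))
  })
  out <- do.call(rbind, rows)
  out[order(out$track_id), ]
}

#' Region-wise quantification of a track set
#'
#' Restricts the ULM readouts to a labelled region of a mask image. Each
#' track is resampled along its polyline (at the fine-grid pitch) and
#' belongs to the region if at least half of its resampled points fall on
#' mask pixels carrying `label` (ties count as inside). The localization
#' counts are per-point: `n_localizations` counts all resampled track points
#' inside the region, `n_upward` / `n_downward` those belonging to tracks
#' classified upward / downward.
#'
#' @param tracks A [link_tracks()] result.
#' @param mask Integer label matrix (axial x lateral), 0 = background,
#'   covering the mapped field at pitch `mask_pitch`.
#' @param label Region label to quantify.
#' @param mask_pitch c(axial, lateral) pitch of the mask in mm/px; defaults
#'   to the acquisition pitch (pass the fine pitch for 10x masks).
#' @param meta An [acquisition_meta()]; taken from `tracks` if `NULL`.
#' @param angle_threshold Dispersity threshold, degrees.
#' @param percentiles Percentiles reported for each metric.
#' @return An object of class `region_quant`: list with `region`,
#'   `n_localizations`, `n_upward`, `n_downward`, `n_tracks`, `metrics` (the
#'   region's per-track table) and `summary` (per-metric mean, sd and
#'   requested percentiles).
#' @export
region_quantify <- function(tracks, mask, label = 1L, mask_pitch = NULL,
                            meta = NULL, angle_threshold = 20,
                            percentiles = c(1, 5, 95, 99)) {
  if (is.null(meta)) meta <- attr(tracks, "meta")
  validate_meta(meta)
  if (is.null(mask_pitch)) {
    mask_pitch <- c(meta$pixel_pitch_axial, meta$pixel_pitch_lateral)
  }
  tl <- track_list(tracks)
  step <- min(mask_pitch) / 10
  inside_pt <- function(pts) {
    ia <- floor(pts[, 1] / mask_pitch[1]) + 1L
    il <- floor(pts[, 2] / mask_pitch[2]) + 1L
    ok <- ia >= 1L & ia <= nrow(mask) & il >= 1L & il <= ncol(mask)
    ins <- logical(nrow(pts))
    ins[ok] <- mask[cbind(ia[ok], il[ok])] == label
    ins
  }
  n_loc <- n_up <- n_down <- 0
  member <- logical(length(tl))
  for (i in seq_along(tl)) {
    pts <- interpolate_track(tl[[i]], step)
    ins <- inside_pt(pts)
    n_in <- sum(ins)
    n_loc <- n_loc + n_in
    dir <- classify_direction(tl[[i]])
    if (dir == "upward") n_up <- n_up + n_in
    if (dir == "downward") n_down <- n_down + n_in
    member[i] <- n_in >= nrow(pts) / 2   # majority, ties inside
  }
  mt <- track_metrics(tracks, meta, angle_threshold)
  mt <- mt[member[match(mt$track_id, as.integer(names(tl)))], , drop = FALSE]
  summarize <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) {
      return(c(n = 0, mean = NA, sd = NA,
               stats::setNames(rep(NA_real_, length(percentiles)),
                               paste0("p", percentiles))))
    }
    c(n = length(v), mean = mean(v), sd = stats::sd(v),
      velocity_percentiles(v, percentiles))
  }
  metric_cols <- c("velocity_mm_s", "dispersity", "tortuosity_deg_mm",
                   "distance_metric", "n_points")
  summ <- t(vapply(metric_cols, function(cn) summarize(mt[[cn]]),
                   numeric(3 + length(percentiles))))
  structure(list(region = label, n_localizations = n_loc, n_upward = n_up,
                 n_downward = n_down, n_tracks = sum(member), metrics = mt,
                 summary = summ),
            class = "region_quant")
}

#' @export
print.region_quant <- function(x, ...) {
  cat(sprintf("region %s: %g localizations (%g up, %g down), %d track(s)\n",
              x$region, x$n_localizations, x$n_upward, x$n_downward,
              x$n_tracks))
  print(round(x$summary, 3))
  invisible(x)
}

#' Percentiles of a flow-velocity distribution
#'
#' Inclusive linear-interpolation percentiles (the convention of
#' [stats::quantile()] type 7): the p-th percentile interpolates between
#' order statistics at rank `1 + (n - 1) p / 100`. The defaults -- 1st, 5th,
#' 95th and 99th -- summarize very slow and very fast flowing structures.
#'
#' @param values Nonempty numeric vector (mm/s).
#' @param percentiles Percentages in `[0, 100]`.
#' @return Named vector, one value per percentile (`p1`, `p5`, ...).
#' @examples
#' velocity_percentiles(1:100)  # p5 = 5.95 under inclusive interpolation
#' @export
velocity_percentiles <- function(values, percentiles = c(1, 5, 95, 99)) {
  if (!length(values)) stop("`values` must be nonempty")
  q <- stats::quantile(values, percentiles / 100, type = 7, names = FALSE)
  stats::setNames(q, paste0("p", percentiles))
}

#' Express a per-timepoint summary relative to baseline
#'
#' Scales a vector of per-timepoint values so the first timepoint (baseline,
#' T1) is 100%.
#'
#' @param values Numeric vector ordered T1, T2, ...; `values[1] > 0`.
#' @return Percentages, same length; first element is 100.
#' @examples
#' relative_to_baseline(c(2, 3))  # 100, 150
#' @export
relative_to_baseline <- function(values) {
  if (!length(values)) stop("`values` must be nonempty")
  if (!is.finite(values[1]) || values[1] <= 0) {
    stop("baseline (first value) must be > 0")
  }
  values / values[1] * 100
}
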