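#' Link localizations into microbubble tracks
#'
#' Frame-to-frame linking with a hard distance gate and globally optimal
#' one-to-one assignment: between the heads of active tracks (their positions
#' in the previous frame) and the localizations of the current frame, the
#' assignment minimizing total Euclidean link cost is chosen among all
#' matchings that respect the gate (equivalently, the matching maximizing
#' `sum(gate - distance)`, solved as a maximum-weight bipartite matching).
#' Unmatched localizations start new tracks; unmatched heads terminate --
#' there is no gap closing. Tracks with fewer than `min_duration`
#' localizations are discarded at the end.
#'
#' Defaults follow the clinical protocol: a maximum linking distance of
#' about two wavelengths (here exactly `2 * wavelength`) and a minimum track
#' duration of 1 frame (single-localization tracks are kept; they contribute
#' to density maps but have no velocity).
#'
#' @param locs A [localize_stack()] result (or anything with columns `frame`,
#'   `axial_mm`, `lateral_mm`, sorted by frame).
#' @param meta An [acquisition_meta()]; taken from `locs` if absent there.
#' @param max_link_distance Gate in mm; default `2 * wavelength`.
#' @param min_duration Minimum localizations per kept track (default 1).
#' @return An object of class `track_set`: a data.frame with columns
#'   `track_id`, `frame`, `axial_mm`, `lateral_mm` (frames consecutive within
#'   a track), with `meta` and linking parameters as attributes.
#' @export
link_tracks <- function(locs, meta = NULL, max_link_distance = NULL,
                        min_duration = 1L) {
  if (is.null(meta)) meta <- attr(locs, "meta")
  validate_meta(meta)
  if (is.null(max_link_distance)) max_link_distance <- 2 * meta$wavelength
  df <- as.data.frame(locs)
  if (nrow(df) == 0) {
    return(new_track_set(data.frame(track_id = integer(0), frame = integer(0),
                                    axial_mm = numeric(0),
                                    lateral_mm = numeric(0)),
                         meta, max_link_distance, min_duration))
  }
  if (is.unsorted(df$frame)) stop("localizations must be sorted by frame")
  df$row <- seq_len(nrow(df))
  by_frame <- split(df, df$frame)
  frames <- as.integer(names(by_frame))

  next_id <- 0L
  heads <- data.frame(track = integer(0), axial = numeric(0),
                      lateral = numeric(0))
  assigned_track <- integer(nrow(df))
  prev_frame <- NULL
  for (fi in seq_along(frames)) {
    cur <- by_frame[[fi]]
    consecutive <- !is.null(prev_frame) && frames[fi] == prev_frame + 1L
    m <- nrow(cur)
    linked_loc <- integer(0); linked_head <- integer(0)
    if (consecutive && nrow(heads) > 0 && m > 0) {
      D <- outer(heads$axial, cur$axial_mm, `-`)^2 +
        outer(heads$lateral, cur$lateral_mm, `-`)^2
      D <- sqrt(D)
      sel <- gated_assignment(D, max_link_distance)
      linked_head <- sel[, 1]; linked_loc <- sel[, 2]
    }
    new_heads <- data.frame(track = integer(m), axial = cur$axial_mm,
                            lateral = cur$lateral_mm)
    for (j in seq_len(m)) {
      k <- match(j, linked_loc)
      if (!is.na(k)) {
        tr <- heads$track[linked_head[k]]
      } else {
        next_id <- next_id + 1L
        tr <- next_id
      }
      assigned_track[cur$row[j]] <- tr
      new_heads$track[j] <- tr
    }
    heads <- new_heads
    prev_frame <- frames[fi]
  }
  df$track_id <- assigned_track
  ## renumber in order of first appearance, drop short tracks
  sizes <- table(df$track_id)
  keep_ids <- names(sizes)[sizes >= min_duration]
  df <- df[df$track_id %in% as.integer(keep_ids), , drop = FALSE]
  df <- df[order(df$track_id, df$frame), ]
  df$track_id <- match(df$track_id, unique(df$track_id))
  out <- df[, c("track_id", "frame", "axial_mm", "lateral_mm")]
  rownames(out) <- NULL
  new_track_set(out, meta, max_link_distance, min_duration,
                n_input = nrow(as.data.frame(locs)))
}

## min-total-distance gated partial assignment on distance matrix D
## (heads x locs); returns cbind(head, loc). Solved as maximum-weight
## bipartite matching with weight gate - d (plus a tiny per-link bonus so
## zero-weight admissible links at exactly the gate remain usable).
gated_assignment <- function(D, gate) {
  allowed <- which(D <= gate, arr.ind = TRUE)
  if (nrow(allowed) == 0) {
    return(cbind(head = integer(0), loc = integer(0)))
  }
  n <- nrow(D)
  w <- (gate - D[allowed]) + gate * 1e-9 + .Machine$double.xmin
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n), rep(TRUE, ncol(D))),
                                    edges = rbind(allowed[, 1],
                                                  n + allowed[, 2]))
  igraph::E(g)$weight <- w
  mt <- igraph::max_bipartite_match(g)$matching
  locs <- mt[seq_len(n)] - n
  keep <- !is.na(locs)
  cbind(head = seq_len(n)[keep], loc = as.integer(locs[keep]))
}

new_track_set <- function(df, meta, max_link_distance, min_duration,
                          n_input = nrow(df)) {
  structure(df, meta = meta,
            params = list(max_link_distance = max_link_distance,
                          min_duration = min_duration),
            n_input_localizations = n_input,
            class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  n_tr <- length(unique(x$track_id))
  cat(sprintf("track_set: %d track(s), %d localizations\n", n_tr, nrow(x)))
  p <- attr(x, "params")
  cat(sprintf("  gate %.3f mm, min duration %d frame(s)\n",
              p$max_link_distance, p$min_duration))
  invisible(x)
}

#' Split a track set into per-track coordinate matrices
#'
#' @param tracks A `track_set`.
#' @return Named list of n x 2 matrices (axial_mm, lateral_mm), one per
#'   track, in track order; frames attached as rownames.
#' @export
track_list <- function(tracks) {
  sp <- split(as.data.frame(tracks), tracks$track_id)
  lapply(sp, function(d) {
    m <- cbind(axial_mm = d$axial_mm, lateral_mm = d$lateral_mm)
    rownames(m) <- d$frame
    m
  })
}

#' Resample a track polyline at fixed arc-length steps
#'
#' Piecewise-linear resampling of the track at arc-length intervals of at
#' most `step`, endpoints included: each original segment is subdivided into
#' equal pieces no longer than `step`, so every resampled point lies exactly
#' on the original polyline and total path length is preserved.
#'
#' @param points n x 2 matrix of track positions in mm (or a single point).
#' @param step Maximum spacing of resampled points in mm.
#' @return m x 2 matrix of resampled positions; a single-point track is
#'   returned unchanged.
#' @export
interpolate_track <- function(points, step) {
  points <- rbind(points)
  if (nrow(points) < 2) return(points)
  if (step <= 0) stop("`step` must be > 0")
  out <- list(points[1, , drop = FALSE])
  for (i in seq_len(nrow(points) - 1)) {
    a <- points[i, ]; b <- points[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n_sub <- max(1L, ceiling(len / step))
    t <- seq_len(n_sub) / n_sub
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  res <- do.call(rbind, out)
  dimnames(res) <- list(NULL, c("axial_mm", "lateral_mm"))
  res
}

#' Write / read a track set as CSV
#'
#' Columns: track_id, frame, axial_mm, lateral_mm. Reading restores a
#' `track_set`, so metrics can run on externally produced tracks.
#'
#' @param tracks A `track_set`.
#' @param path CSV path.
#' @param meta An [acquisition_meta()] to attach on read.
#' @return The path (write) or a `track_set` (read).
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, meta = acquisition_meta()) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "axial_mm", "lateral_mm")
  if (!all(need %in% names(df))) {
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  }
  new_track_set(df[, need], meta,
                max_link_distance = NA_real_, min_duration = NA_integer_)
}
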