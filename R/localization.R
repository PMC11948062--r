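#' Detect candidate microbubble pixels in one frame
#'
#' Local maxima (8-neighborhood) brighter than a robust noise-based
#' threshold, `median + threshold_k * MAD` of the frame. Maxima closer
#' together than `min_separation_px` (Euclidean, in px) keep only the
#' brighter one; exact intensity ties are broken toward the smaller axial,
#' then smaller lateral index. Maxima within `patch_halfwidth` pixels of the
#' frame border are discarded so the refinement patch always fits.
#'
#' @param frame Nonnegative 2-D intensity matrix (axial x lateral).
#' @param threshold_k MAD multiplier of the detection threshold (default 4).
#' @param min_separation_px Minimum distance between kept maxima in px.
#' @param patch_halfwidth Border margin / refinement patch half width in px.
#' @return data.frame with 0-based pixel indices `axial_px`, `lateral_px` and
#'   `intensity`, ordered by decreasing intensity (ties by index).
#' @export
detect_candidates <- function(frame, threshold_k = 4, min_separation_px = 2,
                              patch_halfwidth = 2) {
  if (any(frame < 0)) stop("`frame` must be nonnegative")
  n <- nrow(frame); m <- ncol(frame)
  thr <- stats::median(frame) + threshold_k * stats::mad(frame)
  h <- patch_halfwidth
  if (n < 2 * h + 1 || m < 2 * h + 1) {
    return(data.frame(axial_px = integer(0), lateral_px = integer(0),
                      intensity = numeric(0)))
  }
  ## local max: >= all 8 neighbors (plateaus resolved by the separation rule)
  is_max <- matrix(TRUE, n, m)
  shifts <- expand.grid(da = -1:1, dl = -1:1)
  shifts <- shifts[!(shifts$da == 0 & shifts$dl == 0), ]
  core_a <- 2:(n - 1); core_l <- 2:(m - 1)
  keep <- matrix(FALSE, n, m)
  keep[core_a, core_l] <- TRUE
  for (s in seq_len(nrow(shifts))) {
    da <- shifts$da[s]; dl <- shifts$dl[s]
    is_max[core_a, core_l] <- is_max[core_a, core_l] &
      (frame[core_a, core_l] >= frame[core_a + da, core_l + dl])
  }
  cand <- which(is_max & keep & frame > thr & frame > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(axial_px = integer(0), lateral_px = integer(0),
                      intensity = numeric(0)))
  }
  ## border margin
  ok <- cand[, 1] > h & cand[, 1] <= n - h & cand[, 2] > h & cand[, 2] <= m - h
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(axial_px = integer(0), lateral_px = integer(0),
                      intensity = numeric(0)))
  }
  inten <- frame[cand]
  ord <- order(-inten, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  inten <- inten[ord]
  ## greedy separation filter, brightest first
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    d2 <- (cand[kept, 1] - cand[i, 1])^2 + (cand[kept, 2] - cand[i, 2])^2
    if (min(d2) >= min_separation_px^2) kept[i] <- TRUE
  }
  data.frame(axial_px = cand[kept, 1] - 1L, lateral_px = cand[kept, 2] - 1L,
             intensity = inten[kept])
}

#' Radial-symmetry sub-pixel center of an intensity patch
#'
#' Closed-form sub-pixel localization of a radially symmetric spot: image
#' gradients are estimated on the staggered midpoint grid between pixel
#' centers; each midpoint defines a line along its gradient direction (for a
#' radially symmetric spot every such line passes through the center), and
#' the center is the weighted least-squares point minimizing the
#' gradient-magnitude-squared-weighted squared perpendicular distance to all
#' lines, divided by the midpoint's distance to the gradient-weighted
#' centroid. The solve is a 2x2 linear system, so the method is
#' deterministic and fast.
#'
#' @param patch Square `(2h+1) x (2h+1)` intensity matrix, `h >= 2`; rows are
#'   axial, columns lateral.
#' @return Numeric length-2, `c(d_axial, d_lateral)`: the center offset in px
#'   relative to the patch center pixel.
#' @examples
#' y <- -3:3
#' patch <- outer(y, y, function(a, l) exp(-((a - 0.3)^2 + (l + 0.2)^2) / 2.88))
#' radial_symmetry_center(patch)  # close to (0.3, -0.2)
#' @export
radial_symmetry_center <- function(patch) {
  n <- nrow(patch)
  if (n != ncol(patch) || n < 5 || n %% 2 == 0) {
    stop("`patch` must be square with odd side >= 5")
  }
  h <- (n - 1) / 2
  mid <- (seq_len(n - 1) - 1) - h + 0.5   # midpoint coords rel. patch center
  ## diagonal derivatives on 2x2 cells, then 3x3 mean smoothing
  du <- patch[-n, -1] - patch[-1, -n]     # along (-axial, +lateral)
  dv <- patch[-n, -n] - patch[-1, -1]     # along (-axial, -lateral)
  du <- smooth3(du); dv <- smooth3(dv)
  gl <- (du - dv) / sqrt(2)               # lateral gradient
  ga <- -(du + dv) / sqrt(2)              # axial gradient
  g2 <- ga^2 + gl^2
  if (sum(g2) <= 0) stop("no radial structure in patch")
  A_mid <- matrix(mid, n - 1, n - 1)               # axial coordinate
  L_mid <- matrix(mid, n - 1, n - 1, byrow = TRUE) # lateral coordinate
  gm <- sqrt(g2)
  ac <- sum(A_mid * gm) / sum(gm)
  lc <- sum(L_mid * gm) / sum(gm)
  dc <- sqrt((A_mid - ac)^2 + (L_mid - lc)^2)
  w <- g2 / pmax(dc, 1e-9)
  ## minimize sum_k w_k * dist(c, line_k)^2 ; line_k through midpoint along g
  gg <- pmax(g2, .Machine$double.xmin)
  uaa <- ga * ga / gg; ual <- ga * gl / gg; ull <- gl * gl / gg
  M11 <- sum(w * (1 - uaa)); M12 <- sum(w * (-ual)); M22 <- sum(w * (1 - ull))
  b1 <- sum(w * ((1 - uaa) * A_mid - ual * L_mid))
  b2 <- sum(w * ((1 - ull) * L_mid - ual * A_mid))
  det <- M11 * M22 - M12 * M12
  if (!is.finite(det) || abs(det) <= 1e-12 * (M11 + M22)^2) {
    stop("no radial structure in patch")
  }
  c(d_axial = (M22 * b1 - M12 * b2) / det,
    d_lateral = (M11 * b2 - M12 * b1) / det)
}

## 3x3 mean filter with edge replication
smooth3 <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  Ap <- rbind(A[1, ], A, A[nr, ])
  Ap <- cbind(Ap[, 1], Ap, Ap[, nc])
  (Ap[1:nr, 1:nc] + Ap[1:nr, 2:(nc + 1)] + Ap[1:nr, 3:(nc + 2)] +
   Ap[2:(nr + 1), 1:nc] + Ap[2:(nr + 1), 2:(nc + 1)] + Ap[2:(nr + 1), 3:(nc + 2)] +
   Ap[3:(nr + 2), 1:nc] + Ap[3:(nr + 2), 2:(nc + 1)] + Ap[3:(nr + 2), 3:(nc + 2)]) / 9
}

#' Localize microbubbles through a filtered clip
#'
#' Runs [detect_candidates()] on every frame and refines each candidate with
#' [radial_symmetry_center()] on its surrounding patch. A candidate whose
#' refined center falls more than 1 px from the candidate pixel, or whose
#' patch has no radial structure, is dropped (divergence guard). Pixel
#' coordinates convert to mm via the pixel pitches with the pixel-center
#' convention (pixel `i`, 0-based, has its center at `i * pitch`).
#'
#' @param filtered A clutter-filtered [frame_stack()].
#' @param threshold_k MAD multiplier of the detection threshold.
#' @param min_separation_px Minimum candidate separation in px; default
#'   `round(wavelength / 2 / pitch)` px.
#' @param patch_halfwidth Refinement patch half width (default 2, 5x5 patch).
#' @return An object of class `ulm_localizations`: data.frame with columns
#'   `frame` (0-based), `axial_mm`, `lateral_mm`, `intensity`, sorted by
#'   (frame, axial, lateral), with the metadata and parameters as attributes.
#' @export
localize_stack <- function(filtered, threshold_k = 4,
                           min_separation_px = NULL, patch_halfwidth = 2) {
  stopifnot(inherits(filtered, "frame_stack"))
  meta <- filtered$meta
  if (is.null(min_separation_px)) {
    min_separation_px <- max(1, round(meta$wavelength / 2 /
                                        meta$pixel_pitch_axial))
  }
  h <- patch_halfwidth
  nf <- n_frames(filtered)
  recs <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- filtered$frames[i, , ]
    cand <- detect_candidates(fr, threshold_k, min_separation_px, h)
    if (nrow(cand) == 0) next
    keep <- logical(nrow(cand))
    ax <- lat <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      a0 <- cand$axial_px[j]; l0 <- cand$lateral_px[j]   # 0-based
      patch <- fr[(a0 - h):(a0 + h) + 1L, (l0 - h):(l0 + h) + 1L]
      off <- tryCatch(radial_symmetry_center(patch), error = function(e) NULL)
      if (is.null(off) || any(abs(off) > 1)) next
      keep[j] <- TRUE
      ax[j] <- (a0 + off[1]) * meta$pixel_pitch_axial
      lat[j] <- (l0 + off[2]) * meta$pixel_pitch_lateral
    }
    if (!any(keep)) next
    recs[[i]] <- data.frame(frame = i - 1L, axial_mm = ax[keep],
                            lateral_mm = lat[keep],
                            intensity = cand$intensity[keep])
  }
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs)) {
    recs <- data.frame(frame = integer(0), axial_mm = numeric(0),
                       lateral_mm = numeric(0), intensity = numeric(0))
  }
  recs <- recs[order(recs$frame, recs$axial_mm, recs$lateral_mm), ]
  rownames(recs) <- NULL
  structure(recs, meta = meta,
            params = list(threshold_k = threshold_k,
                          min_separation_px = min_separation_px,
                          patch_halfwidth = patch_halfwidth),
            class = c("ulm_localizations", "data.frame"))
}

#' @export
print.ulm_localizations <- function(x, ...) {
  cat(sprintf("ulm_localizations: %d localizations over %d frame(s)\n",
              nrow(x), length(unique(x$frame))))
  if (nrow(x)) print.data.frame(utils::head(x, 4), row.names = FALSE)
  invisible(x)
}

#' Write / read localizations as CSV
#'
#' Columns: frame, axial_mm, lateral_mm, intensity.
#'
#' @param locs A `ulm_localizations` object.
#' @param path CSV path.
#' @param meta An [acquisition_meta()] to attach on read.
#' @return The path (write) or a `ulm_localizations` (read).
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path, meta = acquisition_meta()) {
  recs <- utils::read.csv(path)
  structure(recs, meta = meta,
            class = c("ulm_localizations", "data.frame"))
}
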