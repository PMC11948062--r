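## shared fixtures, built in code

## square patch sampling an isotropic Gaussian at a sub-pixel offset from the
## patch center; h = half width, offsets in px
gauss_patch <- function(h, d_axial = 0, d_lateral = 0, sigma = 1.2,
                        amplitude = 1) {
  px <- -h:h
  amplitude * exp(-(outer((px - d_axial)^2, (px - d_lateral)^2, `+`)) /
                    (2 * sigma^2))
}

## stack of frames each holding one Gaussian bubble at given 0-based px
## positions (n x 2 matrix), on a side x side grid
bubble_stack <- function(positions, side = 21L, sigma_px = 1.635,
                         meta = acquisition_meta()) {
  positions <- rbind(positions)
  frames <- array(0, dim = c(nrow(positions), side, side))
  px <- 0:(side - 1)
  for (i in seq_len(nrow(positions))) {
    frames[i, , ] <- exp(-(outer((px - positions[i, 1])^2,
                                 (px - positions[i, 2])^2, `+`)) /
                           (2 * sigma_px^2))
  }
  frame_stack(frames, meta)
}

## one straight lateral vessel phantom
straight_vessel <- function(depth = 10, lat0 = 5, lat1 = 25,
                            radius = 0.05, speed = 4, fov = c(20, 30)) {
  vessel_phantom(list(list(centerline = rbind(c(depth, lat0), c(depth, lat1)),
                           radius = radius, speed = speed)), fov)
}

## a track_set built directly from a data.frame of points
manual_tracks <- function(df, meta = acquisition_meta(), gate = NULL) {
  ulmpipe:::new_track_set(df, meta,
                          max_link_distance = gate %||% (2 * meta$wavelength),
                          min_duration = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## regular polyline approximating a semicircle of radius r (n points)
semicircle_track <- function(n = 100, r = 1) {
  th <- seq(0, pi, length.out = n)
  cbind(axial_mm = r * sin(th), lateral_mm = r * (1 - cos(th)))
}
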