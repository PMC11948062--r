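test_that("vessel phantom geometry is validated and preserved", {
  ph <- straight_vessel()
  expect_s3_class(ph, "vessel_phantom")
  expect_length(ph$segments, 1)
  expect_equal(ph$segments[[1]]$length, 20)

  ## two parallel vessels keep their separation everywhere
  ph2 <- vessel_phantom(list(
    list(centerline = rbind(c(10.0, 2), c(10.0, 28)), radius = 0.05, speed = 2),
    list(centerline = rbind(c(10.2, 2), c(10.2, 28)), radius = 0.05, speed = 2)),
    c(20, 30))
  expect_length(ph2$segments, 2)
  expect_equal(ph2$segments[[2]]$centerline[, 1] -
                 ph2$segments[[1]]$centerline[, 1], c(0.2, 0.2))

  ## out-of-field centerline is rejected, naming the segment
  expect_error(
    vessel_phantom(list(list(centerline = rbind(c(10, -1), c(10, 5)),
                             radius = 0.05, speed = 2)), c(20, 30)),
    "segment 1.*field of view")
})

test_that("bubbles advance by speed/frame_rate along the centerline", {
  meta <- acquisition_meta(frame_rate = 10)
  ph <- straight_vessel(speed = 2, radius = 1e-9)
  truth <- simulate_bubbles(ph, meta, n_bubbles = 1, duration = 1.5, seed = 7)
  tr <- truth$trajectories
  expect_gt(nrow(tr), 1)
  steps <- sqrt(diff(tr$axial_mm)^2 + diff(tr$lateral_mm)^2)
  expect_equal(steps, rep(0.2, length(steps)), tolerance = 1e-9)
  expect_equal(tr$frame, tr$frame[1] + seq_len(nrow(tr)) - 1L)
})

test_that("bubble simulation is deterministic and respects the tube", {
  meta <- acquisition_meta()
  ph <- straight_vessel(speed = 3, radius = 0.08)
  a <- simulate_bubbles(ph, meta, n_bubbles = 40, duration = 5, seed = 11)
  b <- simulate_bubbles(ph, meta, n_bubbles = 40, duration = 5, seed = 11)
  expect_identical(a$trajectories, b$trajectories)
  ## geometric containment: distance to the (straight) centerline <= radius
  expect_true(all(abs(a$trajectories$axial_mm - 10) <= 0.08 + 1e-12))
  ## different seed gives a different draw
  c_ <- simulate_bubbles(ph, meta, n_bubbles = 40, duration = 5, seed = 12)
  expect_false(identical(a$trajectories, c_$trajectories))
})

test_that("mean per-frame step matches the imposed speed", {
  meta <- acquisition_meta()
  ph <- straight_vessel(speed = 4, radius = 0.05, lat0 = 1, lat1 = 29)
  truth <- simulate_bubbles(ph, meta, n_bubbles = 500, duration = 10,
                            seed = 21)
  tr <- truth$trajectories
  steps <- unlist(lapply(split(tr, tr$bubble_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    sqrt(diff(d$axial_mm)^2 + diff(d$lateral_mm)^2)
  }))
  expect_gt(length(steps), 1000)
  expect_equal(mean(steps), 4 / meta$frame_rate, tolerance = 0.02)
})

test_that("rendering reproduces bubbles, clutter rank and determinism", {
  meta <- acquisition_meta()
  ph <- straight_vessel(fov = c(6, 6), depth = 3, lat0 = 1, lat1 = 5,
                        radius = 1e-9, speed = 0)
  truth <- simulate_bubbles(ph, meta, n_bubbles = 1, duration = 1, seed = 2)

  ## clutter-free, noise-free: argmax at the bubble pixel in each frame
  clip <- render_movie(truth, meta, clutter_amplitude = 0, noise_sigma = 0,
                       seed = 3)
  tr <- truth$trajectories
  for (k in seq_len(nrow(tr))) {
    fr <- clip$frames[tr$frame[k] + 1L, , ]
    ij <- which(fr == max(fr), arr.ind = TRUE)[1, ]
    expect_equal(unname(ij[1] - 1L), round(tr$axial_mm[k] / 0.1))
    expect_equal(unname(ij[2] - 1L), round(tr$lateral_mm[k] / 0.1))
  }

  ## no bubbles, rank-1 clutter, no noise: frames differ only by a gain
  clip1 <- render_movie(truth, meta, bubble_amplitude = 0, clutter_rank = 1,
                        noise_sigma = 0, seed = 5)
  f1 <- clip1$frames[1, , ]
  f2 <- clip1$frames[7, , ]
  expect_equal(f2 / f1, matrix(mean(f2 / f1), nrow(f1), ncol(f1)),
               tolerance = 1e-9)

  ## rank-3 clutter: Casorati matrix has at most 3 significant singular values
  truth2 <- simulate_bubbles(ph, meta, n_bubbles = 1, duration = 3, seed = 2)
  clip3 <- render_movie(truth2, meta, bubble_amplitude = 0, clutter_rank = 3,
                        noise_sigma = 0, seed = 6)
  d <- dim(clip3$frames)
  X <- matrix(aperm(clip3$frames, c(2, 3, 1)), d[2] * d[3], d[1])
  sv <- svd(X, nu = 0, nv = 0)$d
  expect_lt(sv[4] / sv[1], 1e-10)

  ## determinism
  c1 <- render_movie(truth, meta, noise_sigma = 0.02, seed = 9)
  c2 <- render_movie(truth, meta, noise_sigma = 0.02, seed = 9)
  expect_identical(c1$frames, c2$frames)
})

test_that("simulated TIC follows the lognormal bolus closed forms", {
  times <- seq(0, 80, by = 0.05)
  ## A = 0: flat baseline
  flat <- simulate_tic(times, A = 0, mu = 1, sigma = 0.5,
                       t0 = 5, baseline = 2)
  expect_equal(flat$intensity, rep(2, length(times)))

  ## peak at t0 + exp(mu - sigma^2)
  tic <- simulate_tic(times, A = 50, mu = 2, sigma = 0.5, t0 = 5,
                      baseline = 1)
  t_peak <- times[which.max(tic$intensity)]
  expect_equal(t_peak, 5 + exp(2 - 0.25), tolerance = 0.06)

  ## unit mass: integral of I - baseline over (t0, Inf) equals A
  mass <- stats::integrate(function(t) {
    lognormal_bolus(t, A = 50, mu = 2, sigma = 0.5, t0 = 5, baseline = 1) - 1
  }, 5, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 50, tolerance = 1e-6)

  ## bolus-weighted arrivals concentrate after t0
  meta <- acquisition_meta()
  ph <- straight_vessel()
  truth <- simulate_bubbles(ph, meta, n_bubbles = 300, duration = 40,
                            arrival_profile = list(A = 1, mu = 2.5,
                                                   sigma = 0.4, t0 = 8),
                            seed = 3)
  entry <- vapply(split(truth$trajectories, truth$trajectories$bubble_id),
                  function(d) min(d$frame), 0) / meta$frame_rate
  expect_gt(min(entry), 8 - 1e-9)
})

test_that("frame stack and phantom truth round-trip through disk", {
  meta <- acquisition_meta()
  ph <- straight_vessel()
  truth <- simulate_bubbles(ph, meta, n_bubbles = 5, duration = 1, seed = 4)
  clip <- render_movie(truth, meta, noise_sigma = 0.01, seed = 5)
  tf <- tempfile(fileext = ".tif")
  write_frame_stack(clip, tf)
  back <- read_frame_stack(tf)
  expect_equal(back$frames, clip$frames, tolerance = 1e-6)
  expect_equal(back$meta$wavelength, meta$wavelength)

  cf <- tempfile(fileext = ".csv")
  write_phantom_truth(truth, cf)
  tr <- read_phantom_truth(cf)
  expect_equal(tr$axial_mm, truth$trajectories$axial_mm)
  unlink(c(tf, paste0(tf, ".meta.yaml"), cf))
})
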