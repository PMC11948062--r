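test_that("track velocity follows path length over duration", {
  ## 10 collinear points spaced 0.2 mm at 10 Hz: 1.8 mm / 0.9 s = 2 mm/s
  p10 <- cbind(rep(1, 10), seq(0, by = 0.2, length.out = 10))
  expect_equal(track_velocity(p10, frame_rate = 10), 2)

  ## 2 points 0.5 mm apart at 14 Hz: 0.5 / (1/14) = 7 mm/s
  p2 <- rbind(c(3, 1), c(3, 1.5))
  expect_equal(track_velocity(p2, frame_rate = 14), 7)

  expect_true(is.na(track_velocity(rbind(c(1, 1)), 14)))
})

test_that("dispersity counts direction changes over total points", {
  straight <- cbind(rep(0, 8), seq_len(8))
  expect_equal(dispersity(straight), 0)

  L <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(dispersity(L), 1 / 3)

  zig <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2))
  expect_equal(dispersity(zig), 3 / 5)

  ## zero-length steps have undefined direction and are skipped
  rep_pt <- rbind(c(0, 0), c(0, 0), c(1, 0))
  expect_equal(dispersity(rep_pt), 0)
})

test_that("tortuosity sums turning angles over the chord", {
  straight <- cbind(rep(0, 5), seq_len(5))
  expect_equal(tortuosity(straight), 0)

  L <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(tortuosity(L), 90 / sqrt(2))

  ## discrete semicircle: turning angles sum to 180 (n-2)/(n-1) degrees,
  ## chord 2 mm; approaches 90 deg/mm as n grows
  n <- 100
  semi <- semicircle_track(n = n, r = 1)
  expected <- 180 * (n - 2) / (n - 1) / 2
  expect_equal(tortuosity(semi), expected, tolerance = 1e-9)
  expect_lt(abs(tortuosity(semi) - 90), 1)

  ## closed track is undefined
  closed <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0))
  expect_true(is.na(tortuosity(closed)))
})

test_that("distance metric is path over chord, >= 1", {
  straight <- cbind(rep(0, 5), seq_len(5))
  expect_equal(distance_metric(straight), 1)

  L <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(distance_metric(L), sqrt(2))

  semi <- semicircle_track(n = 100, r = 1)
  expect_lt(abs(distance_metric(semi) - pi / 2), 1e-3)

  expect_true(is.na(distance_metric(rbind(c(0, 0), c(1, 0), c(0, 0)))))
})

test_that("metrics transform correctly under coordinate scaling", {
  set.seed(4)
  p <- cbind(cumsum(stats::runif(7, -0.2, 0.5)) + 3,
             cumsum(stats::runif(7, 0.1, 0.4)) + 1)
  s <- 2.5
  expect_equal(track_velocity(s * p, 14), s * track_velocity(p, 14))
  expect_equal(tortuosity(s * p), tortuosity(p) / s)
  expect_equal(dispersity(s * p), dispersity(p))
  expect_equal(distance_metric(s * p), distance_metric(p))
})

test_that("tortuosity and dispersity vanish together on clean tracks", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    p <- cbind(cumsum(stats::runif(n, -0.5, 0.5)),
               cumsum(stats::runif(n, 0.1, 0.5)))
    t0 <- tortuosity(p) == 0
    d0 <- dispersity(p, angle_threshold = 0) == 0
    expect_equal(t0, d0)
  }
})

test_that("track_metrics assembles per-track records with NA rules", {
  meta <- acquisition_meta()
  df <- rbind(
    data.frame(track_id = 1L, frame = 0:2, axial_mm = c(5, 5, 5),
               lateral_mm = c(1, 1.5, 2)),
    data.frame(track_id = 2L, frame = 0L, axial_mm = 7, lateral_mm = 1),
    data.frame(track_id = 3L, frame = 0:2, axial_mm = c(3, 4, 3),
               lateral_mm = c(1, 1, 1)))
  mt <- track_metrics(manual_tracks(df), meta)
  expect_equal(nrow(mt), 3)
  r1 <- mt[mt$track_id == 1, ]
  expect_equal(r1$velocity_mm_s, 1 / (2 / 14))
  expect_equal(r1$distance_metric, 1)
  expect_equal(r1$direction, "neutral")
  ## single-point track: no velocity, still counted
  r2 <- mt[mt$track_id == 2, ]
  expect_true(is.na(r2$velocity_mm_s))
  expect_equal(r2$n_points, 1)
  ## closed track: tortuosity and DM undefined, velocity defined
  r3 <- mt[mt$track_id == 3, ]
  expect_true(is.na(r3$tortuosity_deg_mm))
  expect_true(is.na(r3$distance_metric))
  expect_equal(r3$velocity_mm_s, 2 / (2 / 14))
})

test_that("velocity percentiles use inclusive linear interpolation", {
  expect_equal(unname(velocity_percentiles(1:100, 5)), 5.95)
  expect_equal(unname(velocity_percentiles(rep(3.2, 17))),
               rep(3.2, 4))
  set.seed(2)
  v <- stats::rlnorm(200)
  q <- velocity_percentiles(v)
  expect_gte(q[["p1"]], min(v))
  expect_lte(q[["p99"]], max(v))
  expect_error(velocity_percentiles(numeric(0)), "nonempty")
})

test_that("baseline-relative changes use T1 = 100%", {
  expect_equal(relative_to_baseline(c(2, 3)), c(100, 150))
  expect_equal(relative_to_baseline(c(5, 5)), c(100, 100))
  expect_error(relative_to_baseline(c(0, 3)), "baseline")
})

test_that("region quantification restricts counts and metrics to the mask", {
  meta <- acquisition_meta()
  ## two tracks, one per half of a 10 x 10 mm field
  df <- rbind(
    data.frame(track_id = 1L, frame = 0:3, axial_mm = seq(2, 2.6, 0.2),
               lateral_mm = seq(1, 2.5, 0.5)),
    data.frame(track_id = 2L, frame = 0:3, axial_mm = seq(8.6, 8, -0.2),
               lateral_mm = seq(1, 2.5, 0.5)))
  tk <- manual_tracks(df)
  mask <- matrix(0L, 101, 101)   # acquisition-pitch mask, 0.1 mm
  mask[1:50, ] <- 1L             # axial < 5 mm
  mask[51:101, ] <- 2L
  top <- region_quantify(tk, mask, label = 1L, meta = meta)
  bottom <- region_quantify(tk, mask, label = 2L, meta = meta)
  expect_equal(top$n_tracks, 1)
  expect_equal(bottom$n_tracks, 1)
  expect_equal(top$metrics$track_id, 1L)
  expect_equal(bottom$metrics$track_id, 2L)
  ## directions: track 1 moves deeper (downward), track 2 toward probe
  expect_equal(top$n_downward, top$n_localizations)
  expect_equal(bottom$n_upward, bottom$n_localizations)
  ## partition property: region point counts sum to the whole-field count
  whole <- region_quantify(tk, matrix(1L, 101, 101), label = 1L, meta = meta)
  expect_equal(top$n_localizations + bottom$n_localizations,
               whole$n_localizations)
  ## empty region
  none <- region_quantify(tk, mask, label = 9L, meta = meta)
  expect_equal(none$n_localizations, 0)
  expect_equal(none$n_tracks, 0)
})
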