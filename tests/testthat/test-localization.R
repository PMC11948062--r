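## independent oracle: dense grid search of the radial-symmetry objective
## (weighted squared distance of a candidate center to all gradient lines),
## with gradients and weights recomputed from scratch
radial_objective <- function(patch, c_ax, c_lat) {
  n <- nrow(patch)
  h <- (n - 1) / 2
  mid <- (seq_len(n - 1) - 1) - h + 0.5
  obj <- 0
  ## centroid pass
  gsum <- 0; asum <- 0; lsum <- 0
  G <- array(0, dim = c(n - 1, n - 1, 2))
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    du <- patch[i, j + 1] - patch[i + 1, j]
    dv <- patch[i, j] - patch[i + 1, j + 1]
    G[i, j, ] <- c(-(du + dv), du - dv) / sqrt(2)   # (axial, lateral)
  }
  ## 3x3 smoothing as in the implementation contract
  Gs <- G
  for (k in 1:2) {
    A <- G[, , k]
    Ap <- rbind(A[1, ], A, A[n - 1, ]); Ap <- cbind(Ap[, 1], Ap, Ap[, n - 1])
    for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
      Gs[i, j, k] <- mean(Ap[i:(i + 2), j:(j + 2)])
    }
  }
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    g2 <- sum(Gs[i, j, ]^2)
    gsum <- gsum + sqrt(g2)
    asum <- asum + mid[i] * sqrt(g2)
    lsum <- lsum + mid[j] * sqrt(g2)
  }
  ac <- asum / gsum; lc <- lsum / gsum
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    g <- Gs[i, j, ]
    g2 <- sum(g^2)
    if (g2 == 0) next
    w <- g2 / max(sqrt((mid[i] - ac)^2 + (mid[j] - lc)^2), 1e-9)
    rel <- c(c_ax - mid[i], c_lat - mid[j])
    proj <- sum(rel * g) / sqrt(g2)
    obj <- obj + w * (sum(rel^2) - proj^2)
  }
  obj
}

test_that("candidate detection handles empty, single and tied inputs", {
  expect_equal(nrow(detect_candidates(matrix(0, 15, 15))), 0)

  f <- gauss_patch(7, 0, 0, sigma = 1.5)
  f <- f + 0   # single bright spot, zero background
  det <- detect_candidates(f, threshold_k = 4, min_separation_px = 3,
                           patch_halfwidth = 2)
  expect_equal(nrow(det), 1)
  expect_equal(det$axial_px, 7)   # 0-based center of a 15x15 patch
  expect_equal(det$lateral_px, 7)

  ## two equal spots 2 px apart with min_separation 5: one survives,
  ## tie broken toward the smaller index
  g <- matrix(0, 15, 15)
  g[7 + 1, 6 + 1] <- 1
  g[7 + 1, 8 + 1] <- 1
  det2 <- detect_candidates(g, threshold_k = 4, min_separation_px = 5,
                            patch_halfwidth = 2)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$lateral_px, 6)

  ## maxima within patch_halfwidth of the border are discarded
  b <- matrix(0, 15, 15)
  b[2, 2] <- 5
  expect_equal(nrow(detect_candidates(b, patch_halfwidth = 2)), 0)
})

test_that("radial symmetry center is exact for a centered spot", {
  off <- radial_symmetry_center(gauss_patch(3, 0, 0, 1.2))
  expect_equal(unname(off), c(0, 0), tolerance = 1e-9)
})

test_that("radial symmetry matches the dense grid-search oracle", {
  cases <- list(c(0.3, -0.2), c(-0.41, 0.13), c(0.05, 0.44))
  for (cs in cases) {
    patch <- gauss_patch(3, cs[1], cs[2], sigma = 1.2)
    est <- radial_symmetry_center(patch)
    ## coarse-to-fine grid search of the same objective, independent code
    grid <- seq(-0.5, 0.5, by = 0.05)
    vals <- outer(grid, grid, Vectorize(function(a, l)
      radial_objective(patch, a, l)))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    fine_a <- seq(grid[ij[1]] - 0.05, grid[ij[1]] + 0.05, by = 0.002)
    fine_l <- seq(grid[ij[2]] - 0.05, grid[ij[2]] + 0.05, by = 0.002)
    vals2 <- outer(fine_a, fine_l, Vectorize(function(a, l)
      radial_objective(patch, a, l)))
    ij2 <- which(vals2 == min(vals2), arr.ind = TRUE)[1, ]
    oracle <- c(fine_a[ij2[1]], fine_l[ij2[2]])
    expect_lt(max(abs(unname(est) - oracle)), 3e-3)
    ## and the recovered center is close to the true sub-pixel offset
    expect_lt(max(abs(unname(est) - cs)), 0.02)
  }
})

test_that("degenerate patches raise a no-radial-structure error", {
  expect_error(radial_symmetry_center(matrix(1, 7, 7)), "radial structure")
  expect_error(radial_symmetry_center(matrix(1, 4, 4)), "odd side")
})

test_that("localize_stack recovers noiseless bubbles to sub-pixel accuracy", {
  set.seed(5)
  n <- 40
  truth <- cbind(10 + stats::runif(n, -0.5, 0.5),
                 10 + stats::runif(n, -0.5, 0.5))
  stack <- bubble_stack(truth)
  locs <- localize_stack(stack)
  expect_equal(nrow(locs), n)
  err <- cbind(locs$axial_mm / 0.1, locs$lateral_mm / 0.1) -
    truth[locs$frame + 1L, ]
  expect_lt(sqrt(mean(err^2)), 0.05)

  ## all-zero stack gives an empty set
  empty <- localize_stack(frame_stack(array(0, dim = c(3, 15, 15)),
                                      acquisition_meta()))
  expect_equal(nrow(empty), 0)
})

test_that("localization is equivariant to integer pixel shifts", {
  pos <- rbind(c(8.3, 9.6))
  s0 <- bubble_stack(pos, side = 25)
  s1 <- bubble_stack(pos + 3, side = 25)   # shift by (+3, +3) px
  l0 <- localize_stack(s0)
  l1 <- localize_stack(s1)
  expect_equal(nrow(l0), 1)
  expect_equal(l1$axial_mm - l0$axial_mm, 0.3, tolerance = 1e-9)
  expect_equal(l1$lateral_mm - l0$lateral_mm, 0.3, tolerance = 1e-9)
})

test_that("sub-pixel estimates are unbiased over uniform offsets", {
  res <- measure_localization_precision(n = 400, snr_db = 30, seed = 99)
  expect_gt(res$n_localized, 380)
  mc_err <- 4 * res$rmse_px / sqrt(res$n_localized)
  expect_lt(abs(res$bias_axial_px), mc_err)
  expect_lt(abs(res$bias_lateral_px), mc_err)
})

test_that("localizations survive a CSV round trip", {
  truth <- rbind(c(9.5, 11.2), c(12.1, 8.8))
  locs <- localize_stack(bubble_stack(truth, side = 25))
  path <- tempfile(fileext = ".csv")
  write_localizations(locs, path)
  back <- read_localizations(path)
  expect_equal(back$axial_mm, locs$axial_mm)
  expect_equal(back$frame, locs$frame)
  unlink(path)
})
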