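noiseless_tic <- function(A = 50, mu = 2, sigma = 0.5, t0 = 5, baseline = 1,
                          times = seq(0, 60, by = 1 / 14)) {
  simulate_tic(times, A = A, mu = mu, sigma = sigma, t0 = t0,
               baseline = baseline, noise_sigma = 0)
}

test_that("TIC extraction averages over the mask", {
  meta <- acquisition_meta()
  frames <- array(3.5, dim = c(6, 8, 9))
  frames[, 2, 2] <- 1:6
  stack <- frame_stack(frames, meta)

  whole <- extract_tic(stack, matrix(TRUE, 8, 9))
  expect_equal(whole$time_s, (0:5) / 14)

  one_px <- matrix(FALSE, 8, 9)
  one_px[2, 2] <- TRUE
  tic <- extract_tic(stack, one_px)
  expect_equal(tic$intensity, as.numeric(1:6))

  expect_error(extract_tic(stack, matrix(FALSE, 8, 9)), "empty")
  expect_error(extract_tic(stack, matrix(TRUE, 3, 3)), "geometry")
})

test_that("bolus fit recovers noiseless parameters within 1%", {
  rec <- measure_tic_recovery(seed = 3)
  expect_lt(rec$max_rel_err, 0.01)
  expect_equal(rec$TTP, rec$TTP_true, tolerance = 1e-6)
})

test_that("fit failures raise bolus_fit_error on degenerate curves", {
  flat <- new_tic <- simulate_tic(seq(0, 30, 0.5), A = 0, mu = 1,
                                  sigma = 0.5, t0 = 2, baseline = 4)
  expect_error(fit_bolus(flat), class = "bolus_fit_error")
  short <- simulate_tic(seq(0, 2, 0.5), A = 10, mu = 0.5, sigma = 0.5,
                        t0 = 0.2, baseline = 1)
  expect_error(fit_bolus(short), class = "bolus_fit_error")
})

test_that("noisy fits stay close over seeded replicates", {
  true <- c(A = 50, mu = 2, sigma = 0.5, t0 = 5, baseline = 1)
  times <- seq(0, 60, by = 1 / 14)
  errs <- sapply(1:10, function(r) {
    tic <- simulate_tic(times, A = 50, mu = 2, sigma = 0.5, t0 = 5,
                        baseline = 1, noise_sigma = 0.05 * 7.3, seed = 100 + r)
    fit <- fit_bolus(tic, seed = r)
    abs(coef(fit)[names(true)] - true) / abs(true)
  })
  ## bias below 5% relative per parameter
  expect_true(all(rowMeans(errs) < 0.05))
})

test_that("derived parameters obey their closed forms and identities", {
  fit <- fit_bolus(noiseless_tic())
  p <- fit$params
  expect_equal(p$TTP, 5 + exp(2 - 0.25), tolerance = 1e-5)
  expect_equal(p$WiWoAUC, p$WiAUC + p$WoAUC)
  expect_equal(p$RT, p$TTP - p$t_in)
  expect_equal(p$FT, p$t_out - p$TTP)
  expect_gt(p$WiR, 0)
  expect_gt(p$WoR, 0)
  expect_gt(p$mTTl, 0)
  expect_equal(p$WiPI, p$WiAUC / p$RT)
  ## the 10% crossing level is respected on the fitted curve
  lvl <- fit$coefficients[["baseline"]] +
    0.1 * (p$PE - fit$coefficients[["baseline"]])
  expect_equal(predict(fit, p$t_in), lvl, tolerance = 1e-6)
  expect_equal(predict(fit, p$t_out), lvl, tolerance = 1e-6)
})

test_that("RT < FT for every lognormal bolus (right skew)", {
  for (mu in c(1, 2, 2.8)) {
    for (sigma in c(0.2, 0.5, 0.9)) {
      tm <- exp(mu - sigma^2)
      tic <- noiseless_tic(A = 30, mu = mu, sigma = sigma, t0 = 2,
                          times = seq(0, 40 + 12 * tm, by = 0.2))
      fit <- fit_bolus(tic)
      p <- fit$params
      expect_lt(p$RT, p$FT)
      ## slower bolus (larger sigma) lengthens both limbs, checked below
    }
  }
  ## a slower bolus -- broader at the same peak time -- lengthens both limbs
  tm <- exp(2 - 0.25)   # fix the mode, widen sigma
  rt_ft <- sapply(c(0.3, 0.5, 0.7), function(sg) {
    fit <- fit_bolus(noiseless_tic(mu = log(tm) + sg^2, sigma = sg,
                                   times = seq(0, 160, 0.2)))
    c(fit$params$RT, fit$params$FT)
  })
  expect_true(all(diff(rt_ft[1, ]) > 0))
  expect_true(all(diff(rt_ft[2, ]) > 0))
})

test_that("amplitude and time-shift equivariances hold", {
  base <- fit_bolus(noiseless_tic())
  s <- 3.7
  scaled_tic <- noiseless_tic()
  scaled_tic$intensity <- scaled_tic$intensity * s
  scaled <- fit_bolus(scaled_tic)
  pb <- base$params; ps <- scaled$params
  for (nm in c("PE", "WiAUC", "WoAUC", "WiR", "WoR", "WiPI")) {
    expect_equal(ps[[nm]], s * pb[[nm]], tolerance = 1e-4)
  }
  for (nm in c("TTP", "RT", "FT", "mTTl")) {
    expect_equal(ps[[nm]], pb[[nm]], tolerance = 1e-4)
  }

  dt <- 4
  shifted <- fit_bolus(noiseless_tic(t0 = 5 + dt))
  expect_equal(shifted$params$TTP, pb$TTP + dt, tolerance = 1e-4)
  for (nm in c("RT", "FT", "mTTl")) {
    expect_equal(shifted$params[[nm]], pb[[nm]], tolerance = 1e-4)
  }
})

test_that("unobserved wash-out marks wash-out parameters unavailable", {
  ## clip ends shortly after the peak: t_out lies beyond the samples
  tic <- noiseless_tic(times = seq(0, 12, by = 1 / 14))
  fit <- fit_bolus(tic)
  expect_false(fit$params$washout_observed)
  expect_true(is.na(fit$params$FT))
  expect_true(is.na(fit$params$WoR))
  expect_true(is.na(fit$params$mTTl))
  expect_false(is.na(fit$params$RT))
})

test_that("model methods are coherent and parameters export to CSV", {
  fit <- fit_bolus(noiseless_tic())
  expect_named(coef(fit), c("A", "mu", "sigma", "t0", "baseline"))
  expect_equal(fitted(fit) + residuals(fit), fit$data$intensity)
  expect_equal(predict(fit, fit$data$time_s), fitted(fit))
  st <- summary(fit)
  expect_equal(nrow(st$table), 11)
  path <- tempfile(fileext = ".csv")
  write_tic_params(fit, path)
  tab <- utils::read.csv(path)
  expect_equal(tab$RT, fit$params$RT, tolerance = 1e-9)
  expect_equal(tab$PE, fit$params$PE, tolerance = 1e-9)
  unlink(path)
})

test_that("a phantom bolus clip yields a TIC matching its arrival profile", {
  meta <- acquisition_meta()
  ph <- straight_vessel(fov = c(8, 12), depth = 4, lat0 = 1, lat1 = 11,
                        radius = 0.05, speed = 3)
  prof <- list(A = 1, mu = 2.2, sigma = 0.45, t0 = 4)
  truth <- simulate_bubbles(ph, meta, n_bubbles = 500, duration = 45,
                            arrival_profile = prof,
                            max_lifetime_frames = 8, seed = 77)
  clip <- render_movie(truth, meta, clutter_amplitude = 0,
                       noise_sigma = 0.001, seed = 78)
  tic <- extract_tic(clip, matrix(TRUE, dim(clip)[2], dim(clip)[3]))
  ref <- lognormal_bolus(tic$time_s, A = 1, mu = prof$mu, sigma = prof$sigma,
                         t0 = prof$t0, baseline = 0)
  ## smooth the per-frame bubble-count fluctuations before comparing
  sm <- stats::filter(tic$intensity, rep(1 / 15, 15), sides = 2)
  keep <- !is.na(sm)
  expect_gt(stats::cor(as.numeric(sm[keep]), ref[keep]), 0.95)
})
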