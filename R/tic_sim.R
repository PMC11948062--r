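#' Lognormal bolus time-intensity model
#'
#' The canonical indicator-dilution model for a contrast bolus: after an
#' arrival delay `t0` the intensity above baseline follows a lognormal
#' density in elapsed time, scaled to total area `A`,
#' \deqn{I(t) = b + \frac{A}{(t-t_0)\sigma\sqrt{2\pi}}
#'   \exp\!\left(-\frac{(\ln(t-t_0)-\mu)^2}{2\sigma^2}\right), \quad t > t_0,}
#' and `I(t) = b` for `t <= t0`. The curve peaks at
#' `t0 + exp(mu - sigma^2)` and integrates (above baseline) to `A`.
#'
#' @param t Time vector in s.
#' @param A Area above baseline (a.u. s), > 0 (0 gives a flat curve).
#' @param mu,sigma Lognormal log-time location and shape; `sigma > 0`.
#' @param t0 Arrival time in s.
#' @param baseline Pre-contrast intensity (a.u.).
#' @return Intensity vector, same length as `t`.
#' @export
lognormal_bolus <- function(t, A, mu, sigma, t0 = 0, baseline = 0) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  out <- rep(baseline, length(t))
  pos <- t > t0
  dt <- t[pos] - t0
  out[pos] <- baseline + A * stats::dlnorm(dt, meanlog = mu, sdlog = sigma)
  out
}

#' Simulate a noisy bolus time-intensity curve
#'
#' Samples the [lognormal_bolus()] model at the given times and adds white
#' Gaussian noise. Used both as the TIC-fitting test input and as the
#' arrival-time weighting of [simulate_bubbles()].
#'
#' @param times Strictly increasing time vector (s).
#' @param A,mu,sigma,t0,baseline Model parameters, see [lognormal_bolus()].
#' @param noise_sigma Noise standard deviation (a.u.).
#' @param seed Integer seed.
#' @param roi Label stored with the curve.
#' @return A `tic` object: data.frame with columns `time_s`, `intensity`,
#'   and attributes `roi`.
#' @examples
#' tic <- simulate_tic(seq(0, 60, by = 1 / 14), A = 50, mu = 2, sigma = 0.5,
#'                     t0 = 5, baseline = 1, noise_sigma = 0)
#' @export
simulate_tic <- function(times, A, mu, sigma, t0 = 0, baseline = 0,
                         noise_sigma = 0, seed = 1L, roi = "roi") {
  if (A < 0) stop("`A` must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  y <- lognormal_bolus(times, A, mu, sigma, t0, baseline)
  if (noise_sigma > 0) {
    set_local_seed(seed)
    y <- y + stats::rnorm(length(times), 0, noise_sigma)
  }
  new_tic(times, y, roi)
}

new_tic <- function(times, intensities, roi = "roi") {
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(data.frame(time_s = times, intensity = intensities),
            roi = roi, class = c("tic", "data.frame"))
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("time-intensity curve '%s': %d samples over %.1f s, peak %.3g\n",
              attr(x, "roi"), nrow(x), diff(range(x$time_s)),
              max(x$intensity)))
  invisible(x)
}
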