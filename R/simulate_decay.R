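## Synthetic 40-bin decay cubes: the per-pixel expected trace is the
## IRF-convolved mono-exponential of the flim module; observations are
## drawn under Gaussian or Poisson noise and averaged over images.

#' A 40-bin instrument response with realistic ringing
#'
#' Gaussian main peak plus a damped oscillation, rectified at zero and
#' normalized to unit sum. A convenient stand-in for a measured
#' second-harmonic IRF.
#'
#' @param n_bins Number of temporal bins (default 40).
#' @param dt Bin width, ns (default 0.3125).
#' @param peak_bin 0-based bin of the IRF peak.
#' @param fwhm_ns Peak full width at half maximum, ns.
#' @param ring_amp Relative ringing amplitude (0 disables).
#' @param ring_period_ns Ringing period, ns.
#' @param ring_damping_ns Ringing envelope decay constant, ns.
#' @return Numeric unit-sum vector of length `n_bins`.
#' @export
ringing_irf <- function(n_bins = 40L, dt = 0.3125, peak_bin = 3,
                        fwhm_ns = 1.0, ring_amp = 0.15,
                        ring_period_ns = 2.5, ring_damping_ns = 1.5) {
  t <- (seq_len(n_bins) - 1) * dt
  t0 <- peak_bin * dt
  u <- exp(-4 * log(2) * (t - t0)^2 / fwhm_ns^2)
  if (ring_amp > 0) {
    d <- t - t0
    on <- d > 0
    u[on] <- u[on] + ring_amp * exp(-d[on] / ring_damping_ns) *
      sin(2 * pi * d[on] / ring_period_ns)
  }
  u <- pmax(u, 0)
  u / sum(u)
}

#' Simulate repeated noisy decay images
#'
#' Draws `n_images` independent noisy realizations of the per-pixel 40-bin
#' expected trace. The expected trace is
#' `convolve_model(u, A, offset, tau)` with `A` scaled so the decay
#' component integrates to `photons_per_pixel` counts per image.
#'
#' @param tau_map Matrix (or vector) of lifetimes, ns, all positive.
#' @param u IRF vector (normalized to unit sum internally).
#' @param photons_per_pixel Expected decay photons per pixel per image.
#'   May be a scalar or an array matching `tau_map`.
#' @param n_images Number of images drawn.
#' @param noise_model `"poisson"` (counts), `"gaussian"` (additive noise
#'   with per-bin sd `sqrt(lambda)`, i.e. shot-matched variance), or
#'   `"none"`.
#' @param offset Constant background level `B` (counts/bin).
#' @param read_noise Additive Gaussian measurement noise per bin per image
#'   (sd, count units): the analog amplifier/digitizer noise floor that
#'   sits on top of photon statistics. Default 0 (pure photon noise).
#' @param seed Integer seed.
#' @return List: `images` (pixels x bins x n_images array), `lambda`
#'   (pixels x bins expected traces), `dims`, `dt`.
#' @export
simulate_decay_images <- function(tau_map, u, photons_per_pixel = 100,
                                  n_images = 1L,
                                  noise_model = c("poisson", "gaussian", "none"),
                                  offset = 0.5, read_noise = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  dims <- dim(tau_map)
  taus <- as.numeric(tau_map)
  if (any(taus <= 0)) stop_invalid("`tau_map` must be positive")
  if (any(u < 0)) stop_invalid("`u` must be non-negative")
  u <- u / sum(u)
  nb <- length(u)
  npix <- length(taus)
  photons <- rep_len(as.numeric(photons_per_pixel), npix)
  lambda <- matrix(0, npix, nb)
  for (p in seq_len(npix)) {
    h <- decay_basis(u, taus[p], nbins = nb)
    A <- photons[p] / sum(h)
    lambda[p, ] <- A * h + offset
  }
  images <- with_seed(seed, {
    arr <- array(0, c(npix, nb, n_images))
    for (i in seq_len(n_images)) {
      img <- switch(noise_model,
        poisson = matrix(rpois(npix * nb, lambda), npix, nb),
        gaussian = lambda + matrix(rnorm(npix * nb, 0, sqrt(lambda)),
                                   npix, nb),
        none = lambda)
      if (read_noise > 0 && noise_model != "none")
        img <- img + matrix(rnorm(npix * nb, 0, read_noise), npix, nb)
      arr[, , i] <- img
    }
    arr
  })
  list(images = images, lambda = lambda, dims = dims, dt = 12.5 / nb)
}

#' Simulate an averaged decay stack
#'
#' Convenience wrapper over [simulate_decay_images()] returning the mean of
#' `n_images` noisy draws as a [decay_stack()]. `n_images = Inf` returns
#' the noiseless expected traces.
#'
#' @inheritParams simulate_decay_images
#' @return A [decay_stack()].
#' @export
simulate_decay_stack <- function(tau_map, u, photons_per_pixel = 100,
                                 n_images = 1L,
                                 noise_model = c("poisson", "gaussian", "none"),
                                 offset = 0.5, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.infinite(n_images) || noise_model == "none") {
    sim <- simulate_decay_images(tau_map, u, photons_per_pixel, 1L,
                                 "none", offset, seed)
    return(decay_stack(sim$lambda, dims = sim$dims, n_images = Inf))
  }
  sim <- simulate_decay_images(tau_map, u, photons_per_pixel, n_images,
                               noise_model, offset = offset, seed = seed)
  cube <- apply(sim$images, c(1, 2), mean)
  decay_stack(cube, dims = sim$dims, n_images = n_images)
}

#' Simulate ROI calcium traces with known baseline
#'
#' Each trace is a slowly drifting baseline (sinusoid + linear trend) plus
#' sparse non-negative exponential-decay transients plus Gaussian noise.
#' The ground-truth baseline and transient-free signal are returned for
#' validating baseline-removal procedures.
#'
#' @param n_rois Number of traces.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param transient_rate Mean transient rate, events/s.
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param drift_amp Amplitude of the slow sinusoidal drift (a.u.).
#' @param drift_period_s Period of the drift, s. Baseline drift
#'   (photobleaching, slow physiology) evolves over minutes, well below
#'   the passband removed by the 30 s baseline smoothing.
#' @param transient_amp Mean transient amplitude (a.u., lognormal).
#' @param tau_decay_s Transient decay constant, s.
#' @return List with `time`, `traces` (n_rois x samples), `baseline`
#'   (same shape) and `events` (list of event-time vectors).
#' @export
simulate_calcium_traces <- function(n_rois = 8L, duration_s = 120,
                                    fs = 15, transient_rate = 0.1,
                                    seed = 1L, noise_sd = 0.02,
                                    drift_amp = 0.1, drift_period_s = 300,
                                    transient_amp = 1, tau_decay_s = 1.5) {
  if (fs <= 0) stop_invalid("`fs` must be positive")
  nt <- round(duration_s * fs)
  time <- (seq_len(nt) - 1) / fs
  with_seed(seed, {
    traces <- baseline <- matrix(0, n_rois, nt)
    events <- vector("list", n_rois)
    for (r in seq_len(n_rois)) {
      phase <- runif(1, 0, 2 * pi)
      slope <- runif(1, -0.05, 0.05) / duration_s
      b <- 1 + drift_amp * sin(2 * pi * time / drift_period_s + phase) +
        slope * time
      n_ev <- rpois(1, transient_rate * duration_s)
      ev <- sort(runif(n_ev, 0, duration_s))
      sig <- numeric(nt)
      for (te in ev) {
        amp <- rlnorm(1, log(transient_amp), 0.3)
        on <- time >= te
        sig[on] <- sig[on] + amp * exp(-(time[on] - te) / tau_decay_s)
      }
      baseline[r, ] <- b
      traces[r, ] <- b + sig + rnorm(nt, 0, noise_sd)
      events[[r]] <- ev
    }
    list(time = time, traces = traces, baseline = baseline, events = events)
  })
}
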