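## Single-photon impulse response of the detection chain: a negative-going
## main lobe followed by a damped oscillation ("ringing") caused by
## residual impedance mismatch in the analog path.

#' Single-photon waveform kernel
#'
#' Builds the sampled response of the PMT/amplifier/digitizer chain to one
#' detected photon: a negative Gaussian-like lobe with the requested FWHM
#' (trough amplitude -1) followed, after a configurable delay, by an
#' exponentially damped sinusoid whose first positive peak lags the trough
#' by `peak_delay_ns`.
#'
#' @param fwhm_ns Full width at half maximum of the negative lobe, ns.
#'   Must span at least two digitizer samples.
#' @param ring_frequency Ringing frequency, Hz.
#' @param ring_damping Ringing amplitude decay rate, 1/s.
#' @param ring_amp Amplitude of the ringing envelope relative to the
#'   (unit) trough; 0 disables ringing.
#' @param peak_delay_ns Trough-to-first-positive-peak delay, ns.
#' @param sample_rate Digitizer rate, samples/s.
#' @return Object of class `single_photon_irf`: list with `kernel`
#'   (numeric), `trough_index` (1-based index of the trough sample),
#'   `fwhm_ns` (configured), `measured_fwhm_ns` (interpolated from the
#'   sampled kernel), `ring_frequency`, `ring_damping`, `sample_rate`.
#' @export
make_photon_kernel <- function(fwhm_ns = 1.875, ring_frequency = 250e6,
                               ring_damping = 2.5e8, ring_amp = 0.25,
                               peak_delay_ns = 2.0, sample_rate = 3.2e9) {
  dt_ns <- 1e9 / sample_rate
  if (fwhm_ns <= 0) stop_invalid("`fwhm_ns` must be positive")
  if (fwhm_ns < 2 * dt_ns)
    stop_invalid("`fwhm_ns` smaller than 2 sample intervals cannot be resolved")
  half <- 3 * fwhm_ns                      # Gaussian support each side
  ring_tail <- if (ring_amp > 0) 5e9 / ring_damping else 0
  t <- seq(-half, half + ring_tail, by = dt_ns) # ns, trough at t = 0
  lobe <- -exp(-4 * log(2) * t^2 / fwhm_ns^2)
  ring <- numeric(length(t))
  if (ring_amp > 0) {
    omega <- 2 * pi * ring_frequency * 1e-9 # rad/ns
    gamma <- ring_damping * 1e-9            # 1/ns
    # start so that the first maximum of exp(-g u) sin(w u) sits at the
    # configured trough-to-peak delay
    u_peak <- atan(omega / gamma) / omega
    t_start <- peak_delay_ns - u_peak
    u <- t - t_start
    on <- u >= 0
    ring[on] <- ring_amp * exp(-gamma * u[on]) * sin(omega * u[on])
  }
  kernel <- lobe + ring
  trough_index <- which.min(kernel)
  structure(list(
    kernel = kernel, trough_index = trough_index, fwhm_ns = fwhm_ns,
    measured_fwhm_ns = measure_fwhm(kernel, trough_index, dt_ns),
    ring_frequency = ring_frequency, ring_damping = ring_damping,
    ring_amp = ring_amp, peak_delay_ns = peak_delay_ns,
    sample_rate = sample_rate
  ), class = "single_photon_irf")
}

## FWHM of a negative lobe by linear interpolation at half-trough level.
measure_fwhm <- function(w, trough, dt) {
  half <- w[trough] / 2 # negative
  cross_left <- NA_real_
  for (i in seq(trough, 2L)) {
    if (w[i - 1] > half && w[i] <= half) {
      frac <- (half - w[i - 1]) / (w[i] - w[i - 1])
      cross_left <- (i - 1) + frac
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(trough, length(w) - 1L)) {
    if (w[i] <= half && w[i + 1] > half) {
      frac <- (half - w[i]) / (w[i + 1] - w[i])
      cross_right <- i + frac
      break
    }
  }
  (cross_right - cross_left) * dt
}

#' @export
print.single_photon_irf <- function(x, ...) {
  cat(sprintf("<single_photon_irf> fwhm %.3g ns (measured %.3g), ring %g MHz amp %.2g\n",
              x$fwhm_ns, x$measured_fwhm_ns, x$ring_frequency / 1e6, x$ring_amp))
  invisible(x)
}
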