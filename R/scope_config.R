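## Acquisition geometry and digitizer settings shared by the simulator and
## the reconstruction chain.

#' Scope / digitizer configuration
#'
#' Bundles the digitizer, laser and scanner parameters of the simulated
#' acquisition. Defaults reproduce the instrument configuration: 3.2 GS/s
#' digitizer, 80 MHz laser (40 samples per pulse period), four excitation
#' paths 3.125 ns apart and two free-running 8 kHz resonant scanners.
#'
#' @param sample_rate Digitizer rate, samples/s. Must be an integer
#'   multiple of `rep_rate`.
#' @param rep_rate Laser repetition rate, Hz.
#' @param n_paths Number of interleaved excitation paths.
#' @param resonant_freq Resonant scanner frequency, Hz (one line per half
#'   period, i.e. one H-sync per sweep).
#' @param fill_fraction Central fraction of the spatial sweep that is
#'   imaged, in (0, 1].
#' @param lines_per_frame,pixels_per_line Output image geometry.
#' @param scanner_phases Length-2 phase offsets (radians) of the two
#'   resonant scanners; they free-run, so their relative phase is
#'   arbitrary.
#' @param noise_sd Additive Gaussian baseline noise of the digitizer
#'   (digitizer units per sample).
#' @param trigger_delay_ns Delay between the laser-clock trigger and the
#'   arrival of path-0 fluorescence (cable delays), ns.
#' @param photon_amp Peak amplitude of a single-photon pulse (digitizer
#'   units; pulses are negative-going).
#' @param seed Optional default seed recorded with the configuration.
#' @return An object of class `scope_config`.
#' @export
scope_config <- function(sample_rate = 3.2e9, rep_rate = 80e6, n_paths = 4L,
                         resonant_freq = 8e3, fill_fraction = 0.9,
                         lines_per_frame = 64L, pixels_per_line = 64L,
                         scanner_phases = c(0, 1.2), noise_sd = 0.02,
                         trigger_delay_ns = 1.0, photon_amp = 1.0,
                         seed = NULL) {
  bins <- sampling_bins(sample_rate, rep_rate) # validates divisibility
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop_invalid("`fill_fraction` must be in (0, 1]")
  if (length(scanner_phases) != 2L)
    stop_invalid("`scanner_phases` must have length 2")
  if (lines_per_frame < 1 || pixels_per_line < 1)
    stop_invalid("frame geometry must be positive")
  structure(list(
    sample_rate = sample_rate, rep_rate = rep_rate,
    n_paths = as.integer(n_paths), resonant_freq = resonant_freq,
    fill_fraction = fill_fraction,
    lines_per_frame = as.integer(lines_per_frame),
    pixels_per_line = as.integer(pixels_per_line),
    scanner_phases = scanner_phases, noise_sd = noise_sd,
    trigger_delay_ns = trigger_delay_ns, photon_amp = photon_amp,
    samples_per_pulse = bins$n_bins, bin_ns = bins$bin_ns,
    period_ns = bins$period_ns, seed = seed
  ), class = "scope_config")
}

#' @export
print.scope_config <- function(x, ...) {
  cat(sprintf(
    "<scope_config> %.3g GS/s, %g MHz laser (%d bins/period), %d paths\n",
    x$sample_rate / 1e9, x$rep_rate / 1e6, x$samples_per_pulse, x$n_paths))
  cat(sprintf("  resonant %g kHz, fill %.2f, %d lines x %d px\n",
              x$resonant_freq / 1e3, x$fill_fraction, x$lines_per_frame,
              x$pixels_per_line))
  invisible(x)
}
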