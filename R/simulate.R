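## Digital twin of the acquisition chain: laser clock, two free-running
## resonant scanners, Poisson photon statistics, single-photon waveform
## kernels and circulant inter-channel leakage, rendered into a sampled
## digitizer stream.

## Resonant scanner kinematics: angle ~ cos(2*pi*f*t + phi); one line per
## half period; an H-sync event marks every sweep boundary (|cos| = 1).
## Boundary k satisfies 2*pi*f*t + phi = k*pi; the sweep starting at an
## even k runs cos +1 -> -1 ("forward").
scanner_sweeps <- function(resonant_freq, phase, n_samples, sample_rate) {
  omega <- 2 * pi * resonant_freq
  t_max <- (n_samples - 1) / sample_rate
  k_lo <- ceiling(phase / pi)
  k_hi <- floor((omega * t_max + phase) / pi)
  k <- seq(k_lo, k_hi)
  t_k <- (k * pi - phase) / omega
  idx <- round(t_k * sample_rate) + 1
  keep <- idx >= 1 & idx <= n_samples
  list(events = idx[keep], k = k[keep],
       first_forward = length(k[keep]) > 0 && k[keep][1] %% 2 == 0)
}

## Spatial pixel address of scanner position x in [-1, 1]: only the
## central +/- fill_fraction is imaged; column 1 sits at x = +ff.
position_to_column <- function(x, fill_fraction, pixels_per_line) {
  u <- (fill_fraction - x) / (2 * fill_fraction)
  col <- floor(u * pixels_per_line) + 1
  col[u < 0 | u >= 1] <- NA_integer_
  col[!is.na(col) & col > pixels_per_line] <- pixels_per_line
  col
}

#' Simulate a multiplexed PMT digitizer stream
#'
#' Renders a full-rate digitizer record of a [phantom()] imaged through the
#' four-path multiplexing scheme. For every laser pulse and path, a Poisson
#' photon count is drawn with mean equal to the phantom brightness at the
#' pixel currently addressed by that path's scanner; each photon is delayed
#' by the path delay, the trigger delay and an exponential lifetime draw,
#' quantized to the digitizer grid, optionally leaked into later channels
#' per the circulant mixing model, and convolved with the single-photon
#' kernel. Gaussian baseline noise is added.
#'
#' Paths are enumerated in acquisition-time order (path 1 direct, path 2
#' direct, path 1 indirect, path 2 indirect): odd-numbered paths follow
#' scanner 1, even-numbered paths scanner 2.
#'
#' @param phantom A [phantom()] with `config$n_paths` brightness maps of
#'   size `lines_per_frame x pixels_per_line`.
#' @param config A [scope_config()].
#' @param mixing Optional [mixing_matrix()]; leakage with coefficients
#'   (a, b, c) is injected cyclically within each pulse period so that the
#'   gated channels obey the mixing model exactly.
#' @param seed Integer seed.
#' @param n_frames Number of frames to simulate.
#' @param kernel Optional [make_photon_kernel()]; default is a 1.875 ns
#'   FWHM ringing kernel at the configured sample rate.
#' @param periodic Wrap photon arrival offsets (decay tail and leakage)
#'   modulo the pulse period. This is the steady-state approximation that
#'   makes the per-pulse circulant mixing exact; disable to let tails
#'   spill into the following record.
#' @return Object of class `raw_stream`: `waveform`, event index vectors
#'   `laser_clock`, `hsync1`, `hsync2`, `vsync` (1-based sample indices),
#'   plus `config`, `mixing`, `kernel`, and per-scanner
#'   `first_sweep_forward` flags.
#' @export
simulate_pmt_stream <- function(phantom, config, mixing = NULL, seed = 1L,
                                n_frames = 1L, kernel = NULL,
                                periodic = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(config, "scope_config"))
  dims <- dim(phantom$tau_map)
  if (dims[1] != config$lines_per_frame || dims[2] != config$pixels_per_line)
    stop_invalid("phantom dimensions do not match the configured geometry")
  if (length(phantom$brightness_maps) != config$n_paths)
    stop_invalid("phantom must provide one brightness map per path")
  if (is.null(kernel))
    kernel <- make_photon_kernel(sample_rate = config$sample_rate)
  fs <- config$sample_rate
  spp <- config$samples_per_pulse
  t_sweep <- 1 / (2 * config$resonant_freq)
  n_samples <- ceiling(fs * (n_frames * config$lines_per_frame + 2.5) * t_sweep)
  laser_clock <- seq(1L, n_samples, by = spp)
  sw1 <- scanner_sweeps(config$resonant_freq, config$scanner_phases[1],
                        n_samples, fs)
  sw2 <- scanner_sweeps(config$resonant_freq, config$scanner_phases[2],
                        n_samples, fs)
  vsync <- round(fs * t_sweep * config$lines_per_frame *
                   (seq_len(n_frames) - 1)) + 1
  spacing_bins <- spp / config$n_paths
  if (abs(spacing_bins - round(spacing_bins)) > 1e-9)
    stop_invalid("samples per period must be divisible by n_paths")
  spacing_bins <- as.integer(round(spacing_bins))
  coefs <- if (is.null(mixing)) c(0, 0, 0) else
    c(mixing$a, mixing$b, mixing$c)

  waveform <- with_seed(seed, {
    t_pulse <- (laser_clock - 1) / fs
    impulses <- numeric(n_samples + spp) # headroom for non-periodic tails
    for (path in seq_len(config$n_paths)) {
      sw <- if (path %% 2 == 1) sw1 else sw2
      phase <- config$scanner_phases[if (path %% 2 == 1) 1 else 2]
      row <- address_rows(laser_clock, sw$events, vsync,
                          config$lines_per_frame)
      x <- cos(2 * pi * config$resonant_freq * t_pulse + phase)
      col <- position_to_column(x, config$fill_fraction,
                                config$pixels_per_line)
      mu <- numeric(length(laser_clock))
      ok <- !is.na(row) & !is.na(col)
      mu[ok] <- phantom$brightness_maps[[path]][cbind(row[ok], col[ok])]
      nph <- rpois(length(mu), mu)
      tot <- sum(nph)
      if (tot == 0) next
      pulse_of <- rep.int(seq_along(nph), nph)
      tau <- numeric(tot)
      okp <- ok[pulse_of]
      tau[okp] <- phantom$tau_map[cbind(row[pulse_of][okp],
                                        col[pulse_of][okp])]
      delay_ns <- config$trigger_delay_ns +
        (path - 1) * spacing_bins * config$bin_ns +
        rexp(tot, rate = 1 / tau)
      off <- round(delay_ns / config$bin_ns)
      if (periodic) off <- off %% spp
      shifts <- c(0L, spacing_bins, 2L * spacing_bins, 3L * spacing_bins)
      amps <- c(config$photon_amp, config$photon_amp * coefs)
      for (s in seq_along(shifts)) {
        if (amps[s] == 0) next
        o <- off + shifts[s]
        if (periodic) o <- o %% spp
        idx <- laser_clock[pulse_of] + o
        keep <- idx >= 1 & idx <= length(impulses)
        tb <- tabulate(idx[keep], nbins = length(impulses))
        impulses <- impulses + amps[s] * tb
      }
    }
    w <- conv_full(impulses, kernel$kernel)
    w <- w[kernel$trough_index:(kernel$trough_index + n_samples - 1)]
    w + rnorm(n_samples, 0, config$noise_sd)
  })

  structure(list(
    waveform = waveform, laser_clock = laser_clock,
    hsync1 = sw1$events, hsync2 = sw2$events, vsync = vsync,
    config = config, mixing = mixing, kernel = kernel,
    first_sweep_forward = c(sw1$first_forward, sw2$first_forward),
    sweep_k0 = c(sw1$k[1], sw2$k[1])
  ), class = "raw_stream")
}

## Row addressed by a pulse: for the frame containing it, line l spans
## [h_{j0+l-1}, h_{j0+l}) where h_{j0} is the first H-sync at/after the
## V-sync. NA outside lines 1..lines_per_frame.
address_rows <- function(clock, hsync, vsync, lines_per_frame) {
  frame <- findInterval(clock, vsync)
  j0 <- findInterval(vsync - 1L, hsync) + 1L # first hsync >= vsync
  sweep <- findInterval(clock, hsync)
  row <- sweep - j0[pmax(frame, 1L)] + 1L
  row[frame < 1L | row < 1L | row > lines_per_frame] <- NA_integer_
  row
}

## Full linear convolution via FFT.
conv_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  xr <- c(x, numeric(nf - length(x)))
  yr <- c(y, numeric(nf - length(y)))
  Re(fft(fft(xr) * fft(yr), inverse = TRUE))[seq_len(n)] / nf
}

#' Mean per-pulse waveform profile (time-resolved calibration)
#'
#' Averages the polarity-corrected waveform over all laser pulses on the
#' 40-bin grid of one pulse period, subtracts the minimum as baseline and
#' clamps at zero. Used with a single-beam acquisition to calibrate
#' inter-channel leakage.
#'
#' @param stream A `raw_stream`.
#' @param polarity `"negative"` (PMT pulses are negative-going) or
#'   `"positive"`.
#' @return Numeric vector of length `samples_per_pulse` (40 at defaults).
#' @export
mean_pulse_profile <- function(stream, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  spp <- stream$config$samples_per_pulse
  clock <- stream$laser_clock
  clock <- clock[clock + spp - 1L <= length(stream$waveform)]
  idx <- outer(clock, 0:(spp - 1L), "+")
  m <- matrix(stream$waveform[idx], nrow = length(clock))
  prof <- colMeans(m)
  if (polarity == "negative") prof <- -prof
  prof <- prof - min(prof)
  pmax(prof, 0)
}
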