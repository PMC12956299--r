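## Closed-form timing, delay-geometry, power-split and focus-correction
## calculations that define the four-way temporal multiplexing scheme.

#' Pulse delays of a temporally multiplexed excitation scheme
#'
#' An 80 MHz laser (inter-pulse interval 12.5 ns) split into `n_paths`
#' equally delayed copies yields pulses spaced `period / n_paths` apart and
#' an effective repetition rate of `rep_rate * n_paths`.
#'
#' @param rep_rate Laser repetition rate in Hz (default 80 MHz).
#' @param n_paths Number of interleaved excitation paths (default 4).
#' @return An object of class `mux_scheme`: a list with `rep_rate`,
#'   `n_paths`, `period` and `spacing` (ns), `path_delays` (ns, one per
#'   path starting at 0) and `effective_rate` (Hz).
#' @examples
#' mux_pulse_delays(80e6, 4)$path_delays # 0, 3.125, 6.25, 9.375 ns
#' @export
mux_pulse_delays <- function(rep_rate = 80e6, n_paths = 4L) {
  if (!is.numeric(rep_rate) || length(rep_rate) != 1L || rep_rate <= 0)
    stop_invalid("`rep_rate` must be a positive frequency in Hz")
  if (!is.numeric(n_paths) || length(n_paths) != 1L || n_paths < 1 ||
      n_paths != round(n_paths))
    stop_invalid("`n_paths` must be a positive integer")
  n_paths <- as.integer(n_paths)
  period <- 1e9 / rep_rate # ns
  spacing <- period / n_paths
  structure(list(
    rep_rate = rep_rate,
    n_paths = n_paths,
    period = period,
    spacing = spacing,
    path_delays = spacing * (seq_len(n_paths) - 1),
    effective_rate = rep_rate * n_paths
  ), class = "mux_scheme")
}

#' @export
print.mux_scheme <- function(x, ...) {
  cat(sprintf("<mux_scheme> %g MHz x %d paths: spacing %g ns, effective %g MHz\n",
              x$rep_rate / 1e6, x$n_paths, x$spacing, x$effective_rate / 1e6))
  invisible(x)
}

#' Free-space path length producing a given optical delay
#'
#' @param delay_ns Delay in nanoseconds (>= 0).
#' @param light_speed Propagation speed in m/s. Defaults to the rounded
#'   3.0e8 m/s convention under which a 6.25 ns loop is quoted as 1.88 m;
#'   pass `299792458` for exact vacuum c.
#' @return Path length in metres.
#' @examples
#' delay_to_path_length(6.25)  # 1.875 m (~1.88)
#' delay_to_path_length(3.125) # 0.9375 m (~0.94)
#' @export
delay_to_path_length <- function(delay_ns, light_speed = 3.0e8) {
  if (any(delay_ns < 0)) stop_invalid("`delay_ns` must be non-negative")
  light_speed * delay_ns * 1e-9
}

#' Four-way power split of the delay-path module
#'
#' Two half-wave-plate / polarizing-beam-splitter pairs set the
#' direct-to-indirect ratio `1:x` and the direct-beam ratio `1:y`. The four
#' output powers are then in ratio `1 : xy : y : x` in the order
#' (path 1 direct, path 1 indirect, path 2 direct, path 2 indirect) and sum
#' to the input power `M` (lossless ideal).
#'
#' @param M Input power (mW), >= 0.
#' @param x Direct-to-indirect split parameter, >= 0.
#' @param y Direct-beam split parameter, >= 0.
#' @return An object of class `power_split` with fields `M`, `x`, `y` and
#'   `powers` (named vector p1D, p1I, p2D, p2I).
#' @examples
#' split_powers(4, 1, 1)$powers # 1 1 1 1
#' @export
split_powers <- function(M, x, y) {
  if (any(c(M, x, y) < 0) || !all(is.finite(c(M, x, y))))
    stop_invalid("`M`, `x` and `y` must be finite and non-negative")
  denom <- (1 + x) * (1 + y)
  powers <- c(p1D = M, p1I = M * x * y, p2D = M * y, p2I = M * x) / denom
  structure(list(M = M, x = x, y = y, powers = powers), class = "power_split")
}

#' Recover (M, x, y) from four measured path powers
#'
#' Inverse of [split_powers()]. The split structure implies the product
#' constraint `p1D * p1I == p2D * p2I`; targets violating it beyond
#' `tol` (relative) are rejected.
#'
#' @param target_powers Numeric length-4 vector (p1D, p1I, p2D, p2I).
#' @param tol Relative tolerance on the product constraint.
#' @return A list with `M`, `x`, `y`.
#' @export
solve_split <- function(target_powers, tol = 1e-6) {
  p <- as.numeric(target_powers)
  if (length(p) != 4L || any(p < 0) || !all(is.finite(p)))
    stop_invalid("`target_powers` must be four finite non-negative powers")
  if (p[1] <= 0)
    stop_invalid("path-1-direct power must be positive to define the ratios")
  lhs <- p[1] * p[2]
  rhs <- p[3] * p[4]
  scale <- max(lhs, rhs, .Machine$double.xmin)
  if (abs(lhs - rhs) / scale > tol)
    stop_invalid("no solution: powers violate the 1:xy:y:x structure ",
                 "(p1D*p1I != p2D*p2I)")
  list(M = sum(p), x = p[4] / p[1], y = p[3] / p[1])
}

#' Focal displacement per unit stage travel
#'
#' With an air-immersion objective and an aqueous specimen, the focus
#' inside the specimen moves 1.35x the axial stage displacement
#' (refractive-index correction used for PSF z-stacks).
#'
#' @param delta_stage Stage displacement (micrometres).
#' @return Focal displacement in the specimen (micrometres).
#' @examples
#' stage_to_focus(1) # 1.35
#' @export
stage_to_focus <- function(delta_stage) 1.35 * delta_stage

#' Fluorescence arrival window of a delayed excitation path
#'
#' If the first path's fluorescence arrives inside `first_window` (ns after
#' the laser trigger), path `path_index` (0-based) arrives
#' `path_index * spacing` later.
#'
#' @param path_index 0-based path index.
#' @param spacing Inter-path delay in ns (3.125 at defaults).
#' @param first_window Numeric length-2 `(lo, hi)` window of path 0, ns.
#' @return Numeric length-2 shifted window (ns).
#' @examples
#' arrival_window(3, 3.125, c(1, 5)) # 12.375 14.375
#' @export
arrival_window <- function(path_index, spacing = 3.125, first_window = c(1, 5)) {
  if (path_index < 0 || path_index != round(path_index))
    stop_invalid("`path_index` must be a non-negative integer")
  if (length(first_window) != 2L || first_window[1] >= first_window[2])
    stop_invalid("`first_window` must be (lo, hi) with lo < hi")
  first_window + path_index * spacing
}

#' Samples stored per pulse record
#'
#' @param duration_ns Record duration in ns (default 15: one pulse period
#'   plus headroom for fluorescence outliving the 12.5 ns period).
#' @param sample_rate Digitizer rate in samples/s.
#' @return Integer sample count (48 at defaults).
#' @export
record_samples <- function(duration_ns = 15, sample_rate = 3.2e9) {
  if (duration_ns <= 0 || sample_rate <= 0)
    stop_invalid("duration and sample rate must be positive")
  as.integer(round(duration_ns * 1e-9 * sample_rate))
}

#' Host-side data rate of the gated channel stream
#'
#' Four 16-bit gate sums per laser pulse give 640 MB/s at 80 MHz.
#'
#' @param rep_rate Laser repetition rate (Hz).
#' @param n_channels Channels stored per pulse.
#' @param bytes_per_value Bytes per stored value (2 for 16-bit).
#' @return Data rate in bytes per second.
#' @export
stream_data_rate <- function(rep_rate = 80e6, n_channels = 4L,
                             bytes_per_value = 2L) {
  rep_rate * n_channels * bytes_per_value
}

#' Per-channel output rate after pulse accumulation
#'
#' @param rep_rate Laser repetition rate (Hz).
#' @param n Accumulation factor (consecutive pulses summed).
#' @return Output rate in Hz (20 MHz for n = 4 at 80 MHz).
#' @export
accumulated_rate <- function(rep_rate = 80e6, n = 4L) {
  if (n < 1) stop_invalid("`n` must be >= 1")
  rep_rate / n
}

#' Temporal bin layout of the digitized pulse period
#'
#' @param sample_rate Digitizer rate (samples/s).
#' @param rep_rate Laser repetition rate (Hz).
#' @return List with `n_bins` (40 at defaults), `bin_ns` (0.3125) and
#'   `period_ns` (12.5).
#' @export
sampling_bins <- function(sample_rate = 3.2e9, rep_rate = 80e6) {
  n <- sample_rate / rep_rate
  if (abs(n - round(n)) > 1e-9)
    stop_invalid("sample rate must be an integer multiple of the rep rate")
  list(n_bins = as.integer(round(n)), bin_ns = 1e9 / sample_rate,
       period_ns = 1e9 / rep_rate)
}
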