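## The FPGA's computation in software: per-pulse record slicing (the
## interleaved odd/even measurement loops), user-defined gate integration
## into four 16-bit channels, and pulse accumulation.

#' Four integration gates within a pulse record
#'
#' Gate endpoints are inclusive 0-based time points within the record
#' (time point 0 = the laser-clock sample). Gates may overlap, but a
#' warning is issued because overlapping gates double-count samples.
#'
#' @param gates List of four `c(start, end)` pairs, or a 4x2 matrix.
#' @param record_len Samples per pulse record (48 at defaults: 15 ns at
#'   3.2 GS/s).
#' @return Object of class `gate_set`.
#' @export
gate_set <- function(gates, record_len = 48L) {
  if (is.matrix(gates)) gates <- lapply(seq_len(nrow(gates)),
                                        function(i) gates[i, ])
  if (length(gates) != 4L) stop_invalid("exactly four gates are required")
  g <- t(vapply(gates, function(x) as.integer(x[1:2]), integer(2)))
  if (any(g[, 1] < 0) || any(g[, 2] >= record_len) || any(g[, 1] > g[, 2]))
    stop_invalid("gates must satisfy 0 <= start <= end < record_len")
  cover <- integer(record_len)
  for (i in 1:4) cover[(g[i, 1]:g[i, 2]) + 1L] <-
    cover[(g[i, 1]:g[i, 2]) + 1L] + 1L
  if (any(cover > 1L)) warning("gates overlap; shared samples are counted in multiple channels")
  structure(list(gates = g, record_len = as.integer(record_len)),
            class = "gate_set")
}

#' Default gate layout for the four-path scheme
#'
#' Four contiguous windows of one inter-path spacing each (10 samples at
#' defaults). The first gate opens `guard_bins` samples before the
#' nominal first-path arrival so the leading edge of the single-photon
#' pulse (which rises ahead of its trough) is captured.
#'
#' @param trigger_delay_ns Trigger-to-first-arrival delay, ns.
#' @param sample_rate Digitizer rate, samples/s.
#' @param rep_rate Laser repetition rate, Hz.
#' @param n_paths Number of paths.
#' @param record_len Samples per record.
#' @param guard_bins Samples the first gate opens ahead of the nominal
#'   arrival (clamped at the record start).
#' @return A [gate_set()].
#' @export
default_gate_set <- function(trigger_delay_ns = 1.0, sample_rate = 3.2e9,
                             rep_rate = 80e6, n_paths = 4L,
                             record_len = 48L, guard_bins = 4L) {
  spp <- sampling_bins(sample_rate, rep_rate)$n_bins
  width <- spp %/% n_paths
  start <- max(0L, round(trigger_delay_ns * 1e-9 * sample_rate) - guard_bins)
  gates <- lapply(0:(n_paths - 1L), function(k) {
    c(start + k * width, start + (k + 1L) * width - 1L)
  })
  gate_set(gates, record_len = record_len)
}

#' Slice a digitizer stream into per-pulse records
#'
#' One record per laser-clock event, starting at the clock sample and
#' spanning `record_len` samples; consecutive records overlap by
#' `record_len - samples_per_period` samples (8 at defaults), mirroring
#' the FPGA's duplicated odd/even measurement loops. Pulses whose record
#' would extend past the waveform end are dropped with a warning.
#'
#' @param stream A `raw_stream` (or a list with `waveform`, `laser_clock`).
#' @param record_len Samples per record.
#' @return Object of class `pulse_records`: matrix `records`
#'   (pulses x record_len) with `pulse_index`, `clock` (sample index of
#'   each record start) and `parity` (0 = odd loop, 1 = even loop).
#' @export
slice_pulse_records <- function(stream, record_len = 48L) {
  waveform <- stream$waveform
  clock <- stream$laser_clock
  if (!length(clock)) stop_invalid("no laser-clock events in stream")
  record_len <- as.integer(record_len)
  ok <- clock + record_len - 1L <= length(waveform)
  if (!all(ok))
    warning(sum(!ok), " trailing pulse(s) dropped: record extends past waveform end")
  keep <- which(ok)
  clock <- clock[keep]
  idx <- outer(clock, 0:(record_len - 1L), "+")
  structure(list(
    records = matrix(waveform[idx], nrow = length(clock)),
    pulse_index = keep, clock = clock,
    parity = (keep - 1L) %% 2L, record_len = record_len
  ), class = "pulse_records")
}

#' Integrate gates over pulse records into channel counts
#'
#' Channel `c` of each pulse is the sum of polarity-corrected,
#' baseline-offset samples over gate `c`, saturated to the 16-bit range
#' (no wraparound). With the default negative polarity, samples enter as
#' `baseline - value`, so photon troughs produce positive counts.
#'
#' @param records A [slice_pulse_records()] result.
#' @param gates A [gate_set()].
#' @param polarity `"negative"` or `"positive"`.
#' @param baseline Baseline level subtracted before summation.
#' @param clip Saturate to `[0, 65535]` (the FPGA's 16-bit storage).
#' @return Object of class `channel_counts`: `values` (pulses x 4),
#'   `pulse_index`, `clock`, `channel_order = "acquisition"`,
#'   `accumulation = 1`.
#' @export
integrate_gates <- function(records, gates, polarity = c("negative", "positive"),
                            baseline = 0, clip = TRUE) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(records, "pulse_records"), inherits(gates, "gate_set"))
  if (gates$record_len > records$record_len ||
      any(gates$gates[, 2] >= records$record_len))
    stop_invalid("gate indices exceed the record length")
  m <- records$records
  m <- if (polarity == "negative") baseline - m else m - baseline
  vals <- vapply(1:4, function(g) {
    cols <- (gates$gates[g, 1]:gates$gates[g, 2]) + 1L
    if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  vals <- matrix(vals, ncol = 4L)
  if (clip) vals <- pmin(pmax(vals, 0), 65535)
  channel_counts(vals, pulse_index = records$pulse_index,
                 clock = records$clock)
}

#' Construct a channel-counts object
#'
#' @param values Pulses x 4 numeric matrix of gate sums.
#' @param pulse_index Integer pulse numbers.
#' @param clock Sample index of each pulse's clock event.
#' @param channel_order Channel ordering tag (`"acquisition"`: gate 0
#'   earliest = path 1D, then 2D, 1I, 2I).
#' @param accumulation Pulses summed per row.
#' @param unmixed Has crosstalk correction been applied.
#' @return Object of class `channel_counts`.
#' @export
channel_counts <- function(values, pulse_index = seq_len(nrow(values)),
                           clock = NULL, channel_order = "acquisition",
                           accumulation = 1L, unmixed = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != 4L) stop_invalid("`values` must have four channels")
  structure(list(values = values, pulse_index = as.integer(pulse_index),
                 clock = clock, channel_order = channel_order,
                 accumulation = as.integer(accumulation), unmixed = unmixed),
            class = "channel_counts")
}

#' Sum consecutive pulses per channel
#'
#' Accumulation compresses the output stream: `n = 4` at 80 MHz yields a
#' 20 MHz per-channel rate. A trailing remainder not divisible by `n` is
#' dropped with a warning.
#'
#' @param counts A [channel_counts()].
#' @param n Accumulation factor: 1, 2 or 4.
#' @return A [channel_counts()] with `accumulation` multiplied by `n`;
#'   `clock`/`pulse_index` keep the first pulse of each group.
#' @export
accumulate_pulses <- function(counts, n) {
  stopifnot(inherits(counts, "channel_counts"))
  if (!n %in% c(1L, 2L, 4L)) stop_invalid("`n` must be 1, 2 or 4")
  n <- as.integer(n)
  if (n == 1L) return(counts)
  np <- nrow(counts$values)
  ng <- np %/% n
  if (np %% n != 0L)
    warning("dropping ", np %% n, " trailing pulse(s) not filling a group")
  keep <- seq_len(ng * n)
  grp <- rep(seq_len(ng), each = n)
  vals <- rowsum(counts$values[keep, , drop = FALSE], grp)
  first <- seq(1L, ng * n, by = n)
  channel_counts(vals, pulse_index = counts$pulse_index[first],
                 clock = counts$clock[first],
                 channel_order = counts$channel_order,
                 accumulation = counts$accumulation * n,
                 unmixed = counts$unmixed)
}
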