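## Single-photon event detection on full-rate waveforms: threshold the
## negative-going PMT pulses, align at the downward crossing, and
## characterize trough, ringing peak and pulse width.

#' Detect single-photon events in a waveform
#'
#' An event starts at a downward threshold crossing and holds off further
#' detections until the waveform rises back above the baseline. For each
#' event the trough, the positive ringing peaks that follow it (within
#' `search_window` samples) and the FWHM of the negative lobe (linear
#' interpolation at half-trough) are measured.
#'
#' @param waveform Numeric sampled waveform (photon pulses negative-going).
#' @param threshold Detection threshold, must lie below `baseline`.
#' @param baseline Baseline level (default 0).
#' @param sample_rate Samples/s (for FWHM in ns).
#' @param search_window Samples after the trough searched for positive
#'   ringing peaks.
#' @return `data.frame` with one row per event: `crossing_index`,
#'   `trough_index`, `trough_amplitude`, `second_peak_index`,
#'   `second_peak_amplitude`, `fwhm_ns`. Empty if no events.
#' @export
detect_photon_events <- function(waveform, threshold, baseline = 0,
                                 sample_rate = 3.2e9,
                                 search_window = 48L) {
  if (threshold >= baseline)
    stop_invalid("`threshold` must lie below `baseline` (negative-going detection)")
  n <- length(waveform)
  below <- waveform < threshold
  crossings <- which(below & !c(FALSE, below[-n]))
  dt_ns <- 1e9 / sample_rate
  out <- list()
  last_end <- 0L
  for (cx in crossings) {
    if (cx <= last_end) next # hold-off: still inside the previous event
    # event extent: until the waveform re-crosses the baseline
    end <- cx
    while (end < n && waveform[end] < baseline) end <- end + 1L
    last_end <- end
    seg <- cx:end
    trough <- seg[which.min(waveform[seg])]
    # positive ringing peaks after the recovery
    win_end <- min(n, trough + search_window)
    pk_idx <- NA_integer_; pk_amp <- NA_real_
    if (win_end > end + 1L) {
      w <- waveform[end:win_end]
      loc <- which(diff(sign(diff(w))) < 0) + 1L # local maxima
      loc <- loc[w[loc] > baseline]
      if (length(loc)) {
        # the waveform's second extremum: the positive ringing peak that
        # follows the (first) trough
        pk_idx <- end + loc[1L] - 1L
        pk_amp <- waveform[pk_idx]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      crossing_index = cx, trough_index = trough,
      trough_amplitude = waveform[trough],
      second_peak_index = pk_idx, second_peak_amplitude = pk_amp,
      fwhm_ns = event_fwhm(waveform, trough, baseline, dt_ns))
  }
  if (!length(out))
    return(data.frame(crossing_index = integer(), trough_index = integer(),
                      trough_amplitude = numeric(),
                      second_peak_index = integer(),
                      second_peak_amplitude = numeric(),
                      fwhm_ns = numeric()))
  do.call(rbind, out)
}

event_fwhm <- function(w, trough, baseline, dt_ns) {
  half <- baseline + (w[trough] - baseline) / 2
  left <- NA_real_; right <- NA_real_
  i <- trough
  while (i > 1L) {
    if (w[i - 1] > half && w[i] <= half) {
      left <- (i - 1) + (half - w[i - 1]) / (w[i] - w[i - 1]); break
    }
    i <- i - 1L
  }
  i <- trough
  while (i < length(w)) {
    if (w[i] <= half && w[i + 1] > half) {
      right <- i + (half - w[i]) / (w[i + 1] - w[i]); break
    }
    i <- i + 1L
  }
  (right - left) * dt_ns
}

#' Summary statistics over detected photon events
#'
#' @param events A [detect_photon_events()] result.
#' @param waveform Optional waveform: if given, an events-by-time alignment
#'   matrix (each row one event aligned at its downward crossing, sorted by
#'   second-peak amplitude, largest first) is included.
#' @param window Samples per aligned row.
#' @return List: `n_events`, `median_fwhm_ns`, `fwhm_ns` (all values),
#'   `trough_peak_corr` (Pearson correlation of trough vs second-peak
#'   sample indices; `NA` with fewer than 2 complete events),
#'   `median_peak_lag` (samples), and optionally `alignment`.
#' @export
photon_event_stats <- function(events, waveform = NULL, window = 48L) {
  n <- nrow(events)
  corr <- NA_real_
  ok <- !is.na(events$second_peak_index)
  if (sum(ok) >= 2L &&
      sd(events$trough_index[ok]) > 0 && sd(events$second_peak_index[ok]) > 0)
    corr <- cor(events$trough_index[ok], events$second_peak_index[ok])
  lag <- NA_real_
  if (any(ok))
    lag <- median(events$second_peak_index[ok] - events$trough_index[ok])
  out <- list(n_events = n,
              median_fwhm_ns = if (n) median(events$fwhm_ns, na.rm = TRUE) else NA_real_,
              fwhm_ns = events$fwhm_ns,
              trough_peak_corr = corr,
              median_peak_lag = lag)
  if (!is.null(waveform) && n > 0) {
    ord <- order(events$second_peak_amplitude, decreasing = TRUE,
                 na.last = TRUE)
    align <- t(vapply(events$crossing_index[ord], function(cx) {
      idx <- cx:(cx + window - 1L)
      v <- rep(NA_real_, window)
      inb <- idx <= length(waveform)
      v[inb] <- waveform[idx[inb]]
      v
    }, numeric(window)))
    out$alignment <- align
  }
  out
}
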