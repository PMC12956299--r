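## ROI time-series processing: neuropil background subtraction and the
## rolling-percentile baseline that sets quiescent activity to zero.

#' Background-subtracted ROI trace
#'
#' Computes the per-frame ROI mean and subtracts the per-frame mean of
#' background pixels within `radius_um` of the ROI, excluding every
#' labelled ROI from the background.
#'
#' @param movie Numeric array `rows x cols x frames`.
#' @param roi_masks Integer label matrix (`rows x cols`), 0 = background.
#' @param roi_id Label of the ROI to extract.
#' @param radius_um Background annulus radius, micrometres (60 by
#'   convention).
#' @param um_per_px Pixel size, micrometres.
#' @return Numeric trace (frames) with attribute `n_background_pixels`.
#' @export
background_subtract <- function(movie, roi_masks, roi_id, radius_um = 60,
                                um_per_px = 1) {
  d <- dim(movie)
  if (length(d) != 3L || !all(d[1:2] == dim(roi_masks)))
    stop_invalid("`movie` must be rows x cols x frames matching `roi_masks`")
  roi <- which(roi_masks == roi_id, arr.ind = TRUE)
  if (!nrow(roi)) stop_invalid("ROI ", roi_id, " not found in masks")
  r_px <- radius_um / um_per_px
  # candidate background pixels: inside the ROI's padded bounding box,
  # unlabelled, within r_px of the nearest ROI pixel
  pad <- ceiling(r_px)
  rr <- max(1, min(roi[, 1]) - pad):min(d[1], max(roi[, 1]) + pad)
  cc <- max(1, min(roi[, 2]) - pad):min(d[2], max(roi[, 2]) + pad)
  cand <- as.matrix(expand.grid(row = rr, col = cc))
  cand <- cand[roi_masks[cand] == 0L, , drop = FALSE]
  if (nrow(cand)) {
    d2 <- outer(cand[, 1], roi[, 1], "-")^2 + outer(cand[, 2], roi[, 2], "-")^2
    cand <- cand[sqrt(apply(d2, 1L, min)) <= r_px, , drop = FALSE]
  }
  if (!nrow(cand))
    stop_invalid("no background pixels within ", radius_um,
                 " um of ROI ", roi_id)
  nf <- d[3]
  mov <- matrix(movie, d[1] * d[2], nf)
  roi_lin <- (roi[, 2] - 1L) * d[1] + roi[, 1]
  bg_lin <- (cand[, 2] - 1L) * d[1] + cand[, 1]
  trace <- colMeans(mov[roi_lin, , drop = FALSE]) -
    colMeans(mov[bg_lin, , drop = FALSE])
  attr(trace, "n_background_pixels") <- nrow(cand)
  trace
}

#' Rolling-percentile baseline and baseline-subtracted trace
#'
#' The baseline of neural activity is estimated as the rolling low
#' percentile (default 8th) of the trace over a centred window (default
#' 15 s), smoothed with a Gaussian filter (default sd 30 s); edges are
#' handled by reflection. Subtracting it sets the quiescent baseline to
#' zero.
#'
#' @param trace Numeric fluorescence trace.
#' @param fs Sampling rate, Hz.
#' @param pct Percentile (0-100).
#' @param window_s Rolling-window length, seconds.
#' @param sigma_s Gaussian smoothing sd, seconds.
#' @param mode `"rolling"` (centred sliding window) or `"tiled"`
#'   (non-overlapping windows, step-interpolated).
#' @param dff Also divide by the baseline (delta-F over F) instead of the
#'   default baseline subtraction (delta-F).
#' @return List: `baseline`, `dff` (same length as `trace`).
#' @export
percentile_baseline <- function(trace, fs, pct = 8, window_s = 15,
                                sigma_s = 30, mode = c("rolling", "tiled"),
                                dff = FALSE) {
  mode <- match.arg(mode)
  if (fs <= 0) stop_invalid("`fs` must be positive")
  n <- length(trace)
  w <- max(1L, round(window_s * fs))
  if (n <= w) stop_invalid("trace shorter than the percentile window")
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  if (mode == "rolling") {
    padded <- c(rev(trace[seq_len(half) + 1L]), trace,
                rev(trace[(n - half):(n - 1L)]))
    roll <- zoo::rollapply(zoo::zoo(padded), width = w,
                           FUN = quantile, probs = pct / 100, names = FALSE,
                           align = "center")
    base_raw <- as.numeric(roll)
  } else {
    starts <- seq(1L, n, by = w)
    q <- vapply(starts, function(s)
      quantile(trace[s:min(n, s + w - 1L)], pct / 100, names = FALSE),
      numeric(1))
    centers <- pmin(starts + half, n)
    base_raw <- approx(centers, q, xout = seq_len(n), rule = 2)$y
  }
  base <- gaussian_smooth(base_raw, sigma_s * fs)
  out <- if (dff) (trace - base) / base else trace - base
  list(baseline = base, dff = out)
}

## Gaussian filter with reflect-padded edges; sigma in samples.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  ri <- min(r, n - 1L)
  padded <- c(rev(x[seq_len(ri) + 1L]), x, rev(x[(n - ri):(n - 1L)]))
  if (ri < r) padded <- c(rep(padded[1], r - ri), padded,
                          rep(padded[length(padded)], r - ri))
  as.numeric(stats::filter(padded, k, sides = 2))[(r + 1L):(r + n)]
}
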