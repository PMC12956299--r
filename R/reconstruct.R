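## Image formation: place per-pulse channel counts into lines using the
## H-sync stream of the matching scanner, correct the bidirectional phase
## offset, resample the sinusoidal sweep onto a uniform spatial grid, and
## export 16-bit TIFF.

#' Frame geometry for reconstruction
#'
#' @param lines_per_frame Lines (H-sync intervals) per frame.
#' @param pulses_per_line Laser pulses kept per sweep.
#' @param pixels_per_line Output pixels per line after desinusoiding.
#' @param fill_fraction Central fraction of the spatial sweep imaged.
#' @param bidirectional Use every sweep (alternate direction) rather than
#'   forward sweeps only.
#' @param first_line_forward Direction of the first line of the frame
#'   (sweep following the first H-sync after the V-sync).
#' @return Object of class `frame_geometry`.
#' @export
frame_geometry <- function(lines_per_frame, pulses_per_line,
                           pixels_per_line, fill_fraction = 0.9,
                           bidirectional = TRUE,
                           first_line_forward = TRUE) {
  if (pixels_per_line > pulses_per_line)
    stop_invalid("`pixels_per_line` cannot exceed `pulses_per_line`")
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop_invalid("`fill_fraction` must be in (0, 1]")
  structure(list(lines_per_frame = as.integer(lines_per_frame),
                 pulses_per_line = as.integer(pulses_per_line),
                 pixels_per_line = as.integer(pixels_per_line),
                 fill_fraction = fill_fraction,
                 bidirectional = isTRUE(bidirectional),
                 first_line_forward = isTRUE(first_line_forward)),
            class = "frame_geometry")
}

#' Frame geometry matching a scope configuration
#'
#' @param config A [scope_config()].
#' @param bidirectional,first_line_forward See [frame_geometry()].
#' @return A [frame_geometry()] whose `pulses_per_line` is the pulse count
#'   of one resonant half-period.
#' @export
geometry_from_config <- function(config, bidirectional = TRUE,
                                 first_line_forward = TRUE) {
  # one fewer than a half-period's pulse budget: clock/H-sync rounding can
  # cost one pulse per sweep, and the sweep extremes lie outside the fill
  # fraction anyway
  ppl <- floor(config$sample_rate / (2 * config$resonant_freq) /
                 config$samples_per_pulse) - 1L
  frame_geometry(config$lines_per_frame, ppl, config$pixels_per_line,
                 fill_fraction = config$fill_fraction,
                 bidirectional = bidirectional,
                 first_line_forward = first_line_forward)
}

#' Direction of the first line of a frame
#'
#' @param stream A `raw_stream` from [simulate_pmt_stream()].
#' @param scanner Scanner index (1 or 2).
#' @param frame Frame number.
#' @return `TRUE` if the first line of the frame is a forward sweep.
#' @export
first_line_direction <- function(stream, scanner = 1L, frame = 1L) {
  hs <- if (scanner == 1L) stream$hsync1 else stream$hsync2
  v <- stream$vsync[frame]
  j0 <- findInterval(v - 1L, hs) + 1L
  k <- stream$sweep_k0[scanner] + (j0 - 1L)
  k %% 2 == 0
}

#' Assemble per-pulse counts into a raw image
#'
#' Pulses between consecutive H-sync events form one line (line 1 starts
#' at the first H-sync at or after the frame's V-sync). Lines swept
#' backward are stored flipped so that columns are spatially consistent,
#' and tagged; the within-sweep phase of every kept pulse is retained for
#' desinusoiding. Path-1 channels (1, 3) must be assembled against
#' H-sync 1 and path-2 channels (2, 4) against H-sync 2; the caller
#' selects the sync stream.
#'
#' @param counts A [channel_counts()] carrying per-pulse `clock` sample
#'   indices.
#' @param hsync H-sync event sample indices of the matching scanner.
#' @param vsync V-sync event sample indices.
#' @param geometry A [frame_geometry()].
#' @param channel Channel to extract (1..4).
#' @param frame Frame number.
#' @return Object of class `raw_image`: `pixels`
#'   (lines x pulses_per_line), `phase` (same shape, within-sweep phase in
#'   `[0, 1)` after direction normalization), `direction` (+1 forward,
#'   -1 backward per line), `channel`, `geometry`.
#' @export
assemble_frame <- function(counts, hsync, vsync, geometry, channel,
                           frame = 1L) {
  stopifnot(inherits(counts, "channel_counts"),
            inherits(geometry, "frame_geometry"))
  if (is.null(counts$clock))
    stop_invalid("`counts` must carry per-pulse clock sample indices")
  if (!channel %in% 1:4) stop_invalid("`channel` must be in 1..4")
  v <- vsync[frame]
  if (is.na(v)) stop_invalid("frame ", frame, " not present in vsync")
  j0 <- findInterval(v - 1L, hsync) + 1L
  nl <- geometry$lines_per_frame
  step <- if (geometry$bidirectional) 1L else 2L
  need <- j0 + step * nl
  if (need > length(hsync))
    stop_invalid("insufficient H-sync events for a complete frame (partial frame)")
  np <- geometry$pulses_per_line
  pix <- phase <- matrix(NA_real_, nl, np)
  dir <- integer(nl)
  vals <- counts$values[, channel]
  for (l in seq_len(nl)) {
    j <- j0 + (l - 1L) * step
    h0 <- hsync[j]; h1 <- hsync[j + 1L]
    sel <- which(counts$clock >= h0 & counts$clock < h1)
    if (length(sel) < np)
      stop_invalid("line ", l, " has only ", length(sel), " pulses (need ",
                   np, ")")
    sel <- sel[seq_len(np)]
    s <- (counts$clock[sel] - h0) / (h1 - h0)
    forward <- xor(!geometry$first_line_forward,
                   (l - 1L) %% 2L == 0L || !geometry$bidirectional)
    if (forward) {
      pix[l, ] <- vals[sel]
      phase[l, ] <- s
      dir[l] <- 1L
    } else {
      pix[l, ] <- rev(vals[sel])
      phase[l, ] <- rev(1 - s)
      dir[l] <- -1L
    }
  }
  structure(list(pixels = pix, phase = phase, direction = dir,
                 channel = as.integer(channel), frame = as.integer(frame),
                 geometry = geometry),
            class = "raw_image")
}

#' Estimate the bidirectional phase offset of a raw image
#'
#' Cross-correlates the mean forward-line profile against the mean
#' (already direction-normalized) backward-line profile over integer
#' column lags, then refines the peak by parabolic interpolation.
#'
#' @param img A `raw_image`.
#' @param max_lag Maximum lag searched, columns.
#' @return Subpixel shift (columns; positive = backward lines lag to the
#'   right) with attribute `low_confidence` set for featureless images.
#' @export
estimate_bidirectional_offset <- function(img, max_lag = 12L) {
  fwd <- img$pixels[img$direction == 1L, , drop = FALSE]
  bwd <- img$pixels[img$direction == -1L, , drop = FALSE]
  if (!nrow(fwd) || !nrow(bwd))
    stop_invalid("bidirectional offset needs both forward and backward lines")
  f <- colMeans(fwd); b <- colMeans(bwd)
  if (sd(f) == 0 || sd(b) == 0)
    return(structure(0, low_confidence = TRUE))
  n <- length(f)
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(k) {
    # positive lag: backward-line content sits k columns to the right
    if (k >= 0) {
      fa <- f[1:(n - k)]; ba <- b[(1 + k):n]
    } else {
      fa <- f[(1 - k):n]; ba <- b[1:(n + k)]
    }
    if (sd(fa) == 0 || sd(ba) == 0) return(-Inf)
    cor(fa, ba)
  }, numeric(1))
  i <- which.max(score)
  shift <- lags[i]
  if (i > 1 && i < length(lags) && all(is.finite(score[(i - 1):(i + 1)]))) {
    y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) shift <- shift + 0.5 * (y1 - y3) / denom
  }
  structure(shift, low_confidence = max(score, na.rm = TRUE) < 0.2)
}

#' Shift backward lines by the estimated bidirectional offset
#'
#' @param img A `raw_image`.
#' @param shift Offset from [estimate_bidirectional_offset()].
#' @return The corrected `raw_image` (backward lines shifted by `-shift`
#'   with linear interpolation, edges held).
#' @export
apply_bidirectional_offset <- function(img, shift) {
  if (shift == 0) return(img)
  n <- ncol(img$pixels)
  for (l in which(img$direction == -1L)) {
    img$pixels[l, ] <- approx(seq_len(n), img$pixels[l, ],
                              xout = seq_len(n) + shift, rule = 2)$y
  }
  img
}

#' Resample a raw image onto a uniform spatial grid (desinusoiding)
#'
#' The resonant scanner position follows `x = cos(pi * s)` over the sweep
#' phase `s` in `[0, 1]`; pulses are uniform in time, hence nonuniform in
#' space. Each line is cropped to the central `fill_fraction` of the sweep
#' and linearly interpolated onto `pixels_per_line` uniformly spaced
#' positions.
#'
#' @param img A `raw_image` (with per-pulse phases).
#' @param geometry Optional [frame_geometry()]; defaults to the image's.
#' @return Object of class `corrected_image`: `pixels`
#'   (lines x pixels_per_line), `channel`, `geometry`.
#' @export
desinusoid <- function(img, geometry = img$geometry) {
  ff <- geometry$fill_fraction
  if (ff <= 0) stop_invalid("`fill_fraction` must be positive")
  npix <- geometry$pixels_per_line
  # pixel centres from +ff (column 1) to -ff, matching the scan direction
  xgrid <- ff * (1 - (2 * seq_len(npix) - 1) / npix)
  nl <- nrow(img$pixels)
  out <- matrix(NA_real_, nl, npix)
  for (l in seq_len(nl)) {
    x <- cos(pi * img$phase[l, ])
    keep <- which(abs(x) <= ff)
    if (length(keep) < 2L)
      stop_invalid("line ", l, " has fewer than 2 pulses inside the fill fraction")
    ord <- keep[order(x[keep])]
    out[l, ] <- approx(x[ord], img$pixels[l, ord], xout = xgrid,
                       rule = 2)$y
  }
  structure(list(pixels = out, channel = img$channel, frame = img$frame,
                 geometry = geometry),
            class = "corrected_image")
}

#' Export images as multi-page 16-bit TIFF
#'
#' Values are scaled by `scale`, rounded, clamped into the 16-bit range
#' (negative values, e.g. from unmixing, are clamped at zero and counted;
#' values above 65535 saturate with a warning) and written losslessly.
#'
#' @param imgs A matrix, a `raw_image`/`corrected_image`, or a list of
#'   them (one page each).
#' @param path Output file path.
#' @param scale Multiplicative scaling before quantization (default 1).
#' @return Invisibly, a list with `n_pages`, `n_negative_clamped`,
#'   `n_saturated`.
#' @export
export_tiff16 <- function(imgs, path, scale = 1) {
  pages <- if (is.list(imgs) && !is.matrix(imgs) &&
               !inherits(imgs, c("raw_image", "corrected_image")))
    imgs else list(imgs)
  mats <- lapply(pages, function(p) {
    if (inherits(p, c("raw_image", "corrected_image"))) p$pixels
    else as.matrix(p)
  })
  n_neg <- 0L; n_sat <- 0L
  quant <- lapply(mats, function(m) {
    v <- round(m * scale)
    n_neg <<- n_neg + sum(v < 0)
    n_sat <<- n_sat + sum(v > 65535)
    pmin(pmax(v, 0), 65535) / 65535
  })
  if (n_neg > 0) warning(n_neg, " negative value(s) clamped to 0 on TIFF export")
  if (n_sat > 0) warning(n_sat, " value(s) saturated at 65535 on TIFF export")
  tiff::writeTIFF(quant, path, bits.per.sample = 16L, compression = "none")
  invisible(list(n_pages = length(quant), n_negative_clamped = n_neg,
                 n_saturated = n_sat))
}

#' Read back a 16-bit TIFF written by [export_tiff16()]
#'
#' @param path TIFF file path.
#' @param scale The scaling used at export (undone on read).
#' @return List of numeric matrices (one per page).
#' @export
read_tiff16 <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * 65535) / scale)
}
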