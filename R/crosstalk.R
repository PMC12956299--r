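## Inter-channel leakage: the fluorescence tail of each 3.125 ns gate
## spills into the gates sampled one, two and three steps later with
## coefficients a, b, c, arranged in a circulant mixing matrix W.
## Correction is applied pulse-by-pulse, before image reconstruction.

#' Circulant channel-mixing model
#'
#' Builds the 4x4 circulant matrix
#' `W = circ(1, a, b, c) = [1 a b c; c 1 a b; b c 1 a; a b c 1]`.
#' In this layout the channel vector is enumerated latest gate first; for
#' count vectors in acquisition-time order (earliest gate first, the
#' package convention) the transpose applies, so that each channel
#' receives `a`, `b`, `c` times the channels gated one, two and three
#' steps earlier (cyclically). [unmix()] handles this automatically.
#'
#' @param a,b,c Leakage coefficients (>= 0) for signals arriving one, two
#'   and three steps earlier.
#' @param cond_cap Maximum admissible condition number of `W`.
#' @return Object of class `mixing_model`: `a`, `b`, `c`, `W`,
#'   `condition_number`.
#' @export
mixing_matrix <- function(a, b, c, cond_cap = 1e6) {
  if (any(c(a, b, c) < 0) || !all(is.finite(c(a, b, c))))
    stop_invalid("leakage coefficients must be finite and non-negative")
  first <- c(1, a, b, c)
  W <- t(vapply(0:3, function(r) first[(((0:3) - r) %% 4) + 1],
                numeric(4)))
  kap <- kappa(W, exact = TRUE)
  if (!is.finite(kap) || kap > cond_cap)
    stop_invalid(sprintf(
      "mixing matrix is ill-conditioned (condition number %.3g > %.3g)",
      kap, cond_cap))
  structure(list(a = a, b = b, c = c, W = W, condition_number = kap),
            class = "mixing_model")
}

#' @export
print.mixing_model <- function(x, ...) {
  cat(sprintf("<mixing_model> circ(1, %.4g, %.4g, %.4g), condition %.3g\n",
              x$a, x$b, x$c, x$condition_number))
  invisible(x)
}

#' Estimate leakage coefficients from a time-resolved calibration profile
#'
#' With a single-beam acquisition sampled on the 40-bin pulse grid, the
#' leakage into the channels gated one, two and three inter-path steps
#' (10 bins) later is the ratio of the profile summed over the main gate
#' shifted cyclically by +10, +20 and +30 bins to the main-gate sum.
#'
#' @param profile Numeric 40-bin mean-intensity trace (baseline
#'   subtracted, non-negative), e.g. from [mean_pulse_profile()].
#' @param main_gate `c(start, end)` inclusive 0-based bins of the gate
#'   containing the profile peak.
#' @param step_bins Bins per inter-path step (10 at defaults).
#' @return Named numeric vector `c(a =, b =, c =)`.
#' @export
estimate_leakage <- function(profile, main_gate, step_bins = 10L) {
  nb <- length(profile)
  idx <- (main_gate[1]:main_gate[2])
  if (any(idx < 0) || any(idx >= nb))
    stop_invalid("`main_gate` outside the profile")
  main <- sum(profile[idx + 1L])
  if (main <= 0) stop_invalid("main-gate sum must be positive")
  ratio <- function(k) sum(profile[((idx + k * step_bins) %% nb) + 1L]) / main
  c(a = ratio(1L), b = ratio(2L), c = ratio(3L))
}

#' Remove inter-channel leakage pulse-by-pulse
#'
#' Applies the inverse mixing model to every pulse's 4-channel count
#' vector (`I = W^-1 J`). Must be applied to per-pulse counts before
#' image reconstruction: the two resonant scanners free-run, so pixels of
#' different paths do not correspond on reconstructed images. Output
#' values are kept in floating point (not re-clipped to 16 bits).
#'
#' @param counts A [channel_counts()] in acquisition-time channel order.
#' @param model A [mixing_matrix()].
#' @return A [channel_counts()] with `unmixed = TRUE`.
#' @export
unmix <- function(counts, model) {
  stopifnot(inherits(counts, "channel_counts"),
            inherits(model, "mixing_model"))
  if (!identical(counts$channel_order, "acquisition"))
    stop_invalid("`counts` must be in acquisition-time channel order")
  # printed W enumerates channels latest-first; transpose for time order
  vals <- t(solve(t(model$W), t(counts$values)))
  channel_counts(vals, pulse_index = counts$pulse_index,
                 clock = counts$clock, channel_order = counts$channel_order,
                 accumulation = counts$accumulation, unmixed = TRUE)
}

#' Apply the mixing model to true counts (forward model)
#'
#' Mostly useful for testing: produces the measured counts `J = W I` that
#' [unmix()] inverts, using the same acquisition-time ordering.
#'
#' @inheritParams unmix
#' @return A [channel_counts()].
#' @export
mix_counts <- function(counts, model) {
  stopifnot(inherits(counts, "channel_counts"),
            inherits(model, "mixing_model"))
  vals <- t(t(model$W) %*% t(counts$values))
  channel_counts(vals, pulse_index = counts$pulse_index,
                 clock = counts$clock, channel_order = counts$channel_order,
                 accumulation = counts$accumulation, unmixed = FALSE)
}
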