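## Fit-free lifetime estimation from the first Fourier harmonic of each
## decay trace, corrected by the IRF's harmonic.

#' Phasor lifetime of a decay trace
#'
#' Both the trace and the IRF are min-max normalized to the zero-one
#' range; their first-harmonic coefficients
#' `g = sum(y cos(theta_k)) / sum(y)`, `s = sum(y sin(theta_k)) / sum(y)`
#' with `theta_k = 2 pi k / n` are combined as complex numbers
#' `C = C1 / C0` (pixel over IRF), and the lifetime follows from the
#' corrected phase: `tau = tan(phi) / omega` with `omega = 2 pi / T`.
#'
#' @param y Decay trace (one pulse period).
#' @param u IRF trace on the same grid.
#' @param dt Bin width, ns.
#' @param normalize Apply the per-trace min-max normalization (the
#'   procedure used on real stacks); disable to use raw traces.
#' @return Object of class `phasor_point`: `g`, `s` (corrected), `g1`,
#'   `s1`, `g0`, `s0`, `phi` (rad), `tau` (ns), `omega` (rad/s),
#'   `undefined` flag for degenerate (constant) traces.
#' @export
phasor_lifetime <- function(y, u, dt = 0.3125, normalize = TRUE) {
  n <- length(y)
  if (length(u) != n) stop_invalid("`y` and `u` must share the bin grid")
  period_s <- n * dt * 1e-9
  omega <- 2 * pi / period_s
  theta <- 2 * pi * (0:(n - 1)) / n
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(NULL)
    (v - r[1]) / (r[2] - r[1])
  }
  yn <- if (normalize) norm01(y) else y
  un <- if (normalize) norm01(u) else u
  if (is.null(yn) || is.null(un) || sum(yn) <= 0 || sum(un) <= 0)
    return(structure(list(g = NA_real_, s = NA_real_, g1 = NA_real_,
                          s1 = NA_real_, g0 = NA_real_, s0 = NA_real_,
                          phi = NA_real_, tau = NA_real_, omega = omega,
                          undefined = TRUE), class = "phasor_point"))
  coef <- function(v) c(sum(v * cos(theta)), sum(v * sin(theta))) / sum(v)
  c1 <- coef(yn); c0 <- coef(un)
  C <- complex(real = c1[1], imaginary = c1[2]) /
    complex(real = c0[1], imaginary = c0[2])
  g <- Re(C); s <- Im(C)
  phi <- atan2(s, g)
  structure(list(g = g, s = s, g1 = c1[1], s1 = c1[2],
                 g0 = c0[1], s0 = c0[2], phi = phi,
                 tau = tan(phi) / omega * 1e9, omega = omega,
                 undefined = FALSE),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("<phasor_point> undefined (constant trace)\n")
  else cat(sprintf("<phasor_point> g %.4f s %.4f, phi %.4f rad, tau %.4g ns\n",
                   x$g, x$s, x$phi, x$tau))
  invisible(x)
}

#' Phasor lifetimes over a decay stack
#'
#' @param stack A [decay_stack()] or pixels x bins matrix.
#' @param u IRF trace.
#' @param dt Bin width, ns.
#' @return Numeric vector of phasor lifetimes (ns), `NA` for degenerate
#'   traces.
#' @export
phasor_image <- function(stack, u, dt = 0.3125) {
  Y <- if (inherits(stack, "decay_stack")) stack$cube else as.matrix(stack)
  apply(Y, 1L, function(y) phasor_lifetime(y, u, dt)$tau)
}
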