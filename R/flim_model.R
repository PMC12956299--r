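## Fluorescence-lifetime estimation: 40-bin decay stacks, the
## IRF-convolved mono-exponential model, least-squares and Poisson
## maximum-likelihood fitting.

#' Construct a decay stack
#'
#' @param cube Pixels x bins matrix of mean counts per bin (40 bins of
#'   0.3125 ns spanning one 12.5 ns pulse period at defaults).
#' @param dims Optional image dimensions `(rows, cols)` with
#'   `prod(dims) == nrow(cube)`.
#' @param dt Bin width, ns.
#' @param n_images Images averaged into the means.
#' @return Object of class `decay_stack`.
#' @export
decay_stack <- function(cube, dims = NULL, dt = 0.3125, n_images = 1) {
  cube <- as.matrix(cube)
  if (any(cube < 0)) stop_invalid("decay stack means must be non-negative")
  if (!is.null(dims) && prod(dims) != nrow(cube))
    stop_invalid("`dims` inconsistent with pixel count")
  structure(list(cube = cube, dims = dims, dt = dt, n_bins = ncol(cube),
                 n_images = n_images),
            class = "decay_stack")
}

#' Assemble a 40-bin stack from windowed acquisitions
#'
#' The digitizer stores four bins per acquisition, so a full 40-bin decay
#' stack is built from 10 sequential acquisitions with stepped window
#' positions. Each acquisition's bins are placed at their true temporal
#' positions; the acquisition order is irrelevant. Missing or overlapping
#' windows are an error.
#'
#' @param window_acquisitions List of acquisitions, each a list with
#'   `bins` (the 0-based bin indices covered, consecutive) and `data`
#'   (pixels x length(bins) matrix).
#' @param n_bins Total bins (40).
#' @param dt Bin width, ns.
#' @return A [decay_stack()].
#' @export
assemble_decay_stack <- function(window_acquisitions, n_bins = 40L,
                                 dt = 0.3125) {
  filled <- logical(n_bins)
  npix <- nrow(as.matrix(window_acquisitions[[1]]$data))
  cube <- matrix(NA_real_, npix, n_bins)
  for (acq in window_acquisitions) {
    bins <- as.integer(acq$bins)
    if (any(bins < 0L) || any(bins >= n_bins))
      stop_invalid("window bins outside 0..", n_bins - 1L)
    if (length(bins) > 1L && any(diff(bins) != 1L))
      stop_invalid("window bins must be consecutive")
    if (any(filled[bins + 1L]))
      stop_invalid("overlapping acquisition windows at bin(s) ",
                   paste(bins[filled[bins + 1L]], collapse = ", "))
    filled[bins + 1L] <- TRUE
    cube[, bins + 1L] <- as.matrix(acq$data)
  }
  if (!all(filled))
    stop_invalid("missing acquisition window(s): bins ",
                 paste(which(!filled) - 1L, collapse = ", "), " uncovered")
  decay_stack(cube, dt = dt)
}

## Mono-exponential folded over three consecutive excitation periods and
## circularly convolved with the IRF. Returns the unit-amplitude decay
## component h (length nbins); the full model is A * h + B * sum(u).
decay_basis <- function(u, tau, dt = 0.3125, nbins = length(u),
                        n_periods = 3L) {
  if (tau <= 0) stop_invalid("`tau` must be positive")
  j <- 0:(n_periods * nbins - 1L)
  e <- exp(-j * dt / tau)
  fold <- rowSums(matrix(e, nbins, n_periods))
  # circular convolution via FFT
  Re(fft(fft(u) * fft(fold), inverse = TRUE)) / nbins
}

## Analytic d h / d tau (same folding).
decay_basis_dtau <- function(u, tau, dt = 0.3125, nbins = length(u),
                             n_periods = 3L) {
  j <- 0:(n_periods * nbins - 1L)
  t <- j * dt
  de <- exp(-t / tau) * t / tau^2
  fold <- rowSums(matrix(de, nbins, n_periods))
  Re(fft(fft(u) * fft(fold), inverse = TRUE)) / nbins
}

#' IRF-convolved mono-exponential decay model
#'
#' Expected per-bin trace `A * (u (*) e^{-t/tau}) + B * sum(u)`, where the
#' exponential is sampled at the bin grid over three consecutive pulse
#' periods (the periodic IRF extension `[u u u]` that avoids wrap-around
#' artefacts at the period boundary) and circularly convolved with the
#' IRF. For a unit-sum IRF the offset term is simply `B`.
#'
#' @param u IRF trace (typically unit-sum normalized).
#' @param A Decay amplitude (counts).
#' @param B Constant offset (counts/bin for unit-sum `u`).
#' @param tau Lifetime, ns (> 0).
#' @param dt Bin width, ns.
#' @return Numeric model trace, `length(u)` bins.
#' @export
convolve_model <- function(u, A, B, tau, dt = 0.3125) {
  A * decay_basis(u, tau, dt = dt) + B * sum(u)
}

## Closed-form (A, B) >= 0 least squares for fixed tau; returns list with
## A, B, rss, fitted.
ls_amplitudes <- function(y, h, su) {
  n <- length(y)
  a11 <- sum(h * h); a12 <- su * sum(h); a22 <- su^2 * n
  b1 <- sum(y * h); b2 <- su * sum(y)
  det <- a11 * a22 - a12^2
  if (det > 1e-12 * a11 * a22 + 1e-300) {
    A <- (a22 * b1 - a12 * b2) / det
    B <- (a11 * b2 - a12 * b1) / det
  } else {
    A <- 0; B <- -1 # degenerate design: fall through to clamping
  }
  if (A < 0) {
    A <- 0
    B <- mean(y) / su
  } else if (B < 0) {
    B <- 0
    A <- max(0, b1 / a11)
  }
  fitted <- A * h + B * su
  list(A = A, B = B, rss = sum((y - fitted)^2), fitted = fitted)
}

#' Least-squares lifetime fit of a 40-bin decay trace
#'
#' Minimizes the sum of squared residuals between the trace and
#' [convolve_model()] over `tau` (coarse log-spaced grid followed by a 1-D
#' bounded search) with the amplitudes `(A, B)` obtained in closed form at
#' each `tau`, constrained non-negative.
#'
#' @param y Numeric decay trace (non-negative means).
#' @param u IRF trace; normalized to unit sum internally.
#' @param tau_range Search bounds for `tau`, ns. The lower default is one
#'   bin width.
#' @param dt Bin width, ns.
#' @param n_grid Coarse-grid size bracketing the optimum.
#' @return Object of class `lifetime_fit`: `A`, `B`, `tau`, `rss`, `corr`
#'   (Pearson correlation of fit vs data), `neg_log_lik` (`NA` for the LS
#'   path), `converged`, `method`.
#' @export
fit_lifetime_ls <- function(y, u, tau_range = c(0.3125, 12.5),
                            dt = 0.3125, n_grid = 40L) {
  if (any(y < 0)) stop_invalid("`y` must be non-negative")
  u <- u / sum(u)
  su <- 1
  grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = n_grid))
  rss_at <- function(tau) ls_amplitudes(y, decay_basis(u, tau, dt), su)$rss
  rss_grid <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- optimize(rss_at, c(lo, hi), tol = 1e-6)
  tau <- opt$minimum
  amp <- ls_amplitudes(y, decay_basis(u, tau, dt), su)
  corr <- if (sd(y) > 0 && sd(amp$fitted) > 0) cor(y, amp$fitted) else NA_real_
  on_bound <- tau <= tau_range[1] * 1.001 || tau >= tau_range[2] * 0.999 ||
    i == 1L || i == n_grid
  structure(list(A = amp$A, B = amp$B, tau = tau, rss = amp$rss,
                 corr = corr, neg_log_lik = NA_real_,
                 converged = amp$A > 0 && !on_bound, method = "ls"),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit:%s> tau %.4g ns, A %.4g, B %.4g, corr %.4f%s\n",
              x$method, x$tau, x$A, x$B, x$corr,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Poisson maximum-likelihood lifetime fit
#'
#' Treats the per-bin counts as independent Poisson with mean
#' `n_images * convolve_model(u, A, B, tau)` and minimizes the negative
#' log-likelihood `sum(lambda - y log lambda)` in `(log A, log B,
#' log tau)` (positivity by construction) with analytic gradients,
#' initialized from the least-squares fit.
#'
#' @param y Decay trace of per-image mean counts.
#' @param u IRF trace; normalized to unit sum internally.
#' @param n_images Images averaged into `y` (total counts are
#'   `n_images * y`).
#' @param tau_range Bounds for `tau`, ns.
#' @param dt Bin width, ns.
#' @param init Optional `lifetime_fit` used as initialization.
#' @return A `lifetime_fit` (with `neg_log_lik`).
#' @export
fit_lifetime_poisson <- function(y, u, n_images = 1,
                                 tau_range = c(0.3125, 12.5),
                                 dt = 0.3125, init = NULL) {
  if (any(y < 0)) stop_invalid("`y` must be non-negative")
  u <- u / sum(u)
  if (is.null(init)) init <- fit_lifetime_ls(y, u, tau_range, dt)
  yy <- y * n_images
  floor_lam <- 1e-10
  p0 <- log(pmax(c(init$A, init$B, init$tau),
                 c(1e-6 * max(mean(y), 1), 1e-6 * max(mean(y), 1),
                   tau_range[1])))
  nll <- function(p) {
    A <- exp(p[1]); B <- exp(p[2]); tau <- exp(p[3])
    lam <- n_images * pmax(A * decay_basis(u, tau, dt) + B, floor_lam)
    sum(lam - yy * log(lam))
  }
  grad <- function(p) {
    A <- exp(p[1]); B <- exp(p[2]); tau <- exp(p[3])
    h <- decay_basis(u, tau, dt)
    lam_raw <- n_images * (A * h + B)
    lam <- pmax(lam_raw, floor_lam)
    w <- (1 - yy / lam) * (lam_raw >= floor_lam)
    dh <- decay_basis_dtau(u, tau, dt)
    c(sum(w * n_images * h) * A,
      sum(w * n_images) * B,
      sum(w * n_images * A * dh) * tau)
  }
  opt <- optim(p0, nll, grad, method = "L-BFGS-B",
               lower = c(-Inf, -Inf, log(tau_range[1])),
               upper = c(Inf, Inf, log(tau_range[2])),
               control = list(maxit = 300L))
  A <- exp(opt$par[1]); B <- exp(opt$par[2]); tau <- exp(opt$par[3])
  fitted <- A * decay_basis(u, tau, dt) + B
  corr <- if (sd(y) > 0 && sd(fitted) > 0) cor(y, fitted) else NA_real_
  structure(list(A = A, B = B, tau = tau, rss = sum((y - fitted)^2),
                 corr = corr, neg_log_lik = opt$value,
                 converged = opt$convergence == 0L, method = "poisson"),
            class = "lifetime_fit")
}

#' Fit lifetimes over a whole decay stack
#'
#' Vectorized per-pixel lifetime estimation. Only pixels brighter than a
#' percentile threshold of the summed trace are fitted; others are `NA`.
#' The least-squares path evaluates a shared `tau` grid for all pixels at
#' once (closed-form amplitudes, parabolic refinement of the grid
#' minimum); the Poisson path runs the per-pixel MLE initialized from the
#' grid solution.
#'
#' @param stack A [decay_stack()] (or pixels x bins matrix).
#' @param u IRF trace.
#' @param method `"ls"` or `"poisson"`.
#' @param threshold_pct Brightness percentile below which pixels are
#'   skipped (0 fits everything).
#' @param tau_range,dt As in [fit_lifetime_ls()].
#' @param n_grid Size of the shared `tau` grid.
#' @param n_images Images averaged (Poisson path).
#' @return List: `tau`, `A`, `B`, `corr` (vectors, `NA` where skipped),
#'   `mask` (fitted pixels), `brightness` (summed trace).
#' @export
fit_lifetime_image <- function(stack, u, method = c("ls", "poisson"),
                               threshold_pct = 50, tau_range = c(0.3125, 12.5),
                               dt = 0.3125, n_grid = 120L, n_images = 1) {
  method <- match.arg(method)
  Y <- if (inherits(stack, "decay_stack")) stack$cube else as.matrix(stack)
  u <- u / sum(u)
  npix <- nrow(Y); nb <- ncol(Y)
  brightness <- rowSums(Y)
  thr <- if (threshold_pct > 0) quantile(brightness, threshold_pct / 100)
         else -Inf
  mask <- brightness >= thr
  grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = n_grid))
  H <- vapply(grid, function(tt) decay_basis(u, tt, dt), numeric(nb))
  Ym <- Y[mask, , drop = FALSE]
  nm <- nrow(Ym)
  sy <- rowSums(Ym); syy <- rowSums(Ym^2)
  rss <- matrix(Inf, nm, n_grid)
  Amat <- Bmat <- matrix(0, nm, n_grid)
  for (g in seq_len(n_grid)) {
    h <- H[, g]
    a11 <- sum(h * h); a12 <- sum(h); a22 <- nb
    b1 <- Ym %*% h; b2 <- sy
    det <- a11 * a22 - a12^2
    A <- (a22 * b1 - a12 * b2) / det
    B <- (a11 * b2 - a12 * b1) / det
    negA <- A < 0
    A[negA] <- 0; B[negA] <- sy[negA] / nb
    negB <- !negA & B < 0
    B[negB] <- 0; A[negB] <- pmax(0, b1[negB] / a11)
    r <- syy - 2 * (A * b1 + B * b2) +
      A^2 * a11 + 2 * A * B * a12 + B^2 * a22
    rss[, g] <- r; Amat[, g] <- A; Bmat[, g] <- B
  }
  gi <- max.col(-rss, ties.method = "first")
  tau_hat <- grid[gi]
  # parabolic refinement on log-tau
  interior <- gi > 1L & gi < n_grid
  if (any(interior)) {
    ii <- which(interior)
    lg <- log(grid)
    y1 <- rss[cbind(ii, gi[ii] - 1L)]
    y2 <- rss[cbind(ii, gi[ii])]
    y3 <- rss[cbind(ii, gi[ii] + 1L)]
    denom <- y1 - 2 * y2 + y3
    ok <- denom > 0
    step <- (lg[2] - lg[1])
    tau_hat[ii[ok]] <- exp(lg[gi[ii[ok]]] +
                             0.5 * step * ((y1 - y3)[ok] / denom[ok]))
  }
  A_hat <- Amat[cbind(seq_len(nm), gi)]
  B_hat <- Bmat[cbind(seq_len(nm), gi)]
  corr_hat <- rep(NA_real_, nm)
  for (p in seq_len(nm)) {
    if (method == "poisson") {
      init <- structure(list(A = max(A_hat[p], 1e-8), B = max(B_hat[p], 1e-8),
                             tau = tau_hat[p]), class = "lifetime_fit")
      f <- fit_lifetime_poisson(Ym[p, ], u, n_images = n_images,
                                tau_range = tau_range, dt = dt, init = init)
      tau_hat[p] <- f$tau; A_hat[p] <- f$A; B_hat[p] <- f$B
      corr_hat[p] <- f$corr
    } else {
      amp <- ls_amplitudes(Ym[p, ], decay_basis(u, tau_hat[p], dt), 1)
      A_hat[p] <- amp$A; B_hat[p] <- amp$B
      corr_hat[p] <- if (sd(Ym[p, ]) > 0 && sd(amp$fitted) > 0)
        cor(Ym[p, ], amp$fitted) else NA_real_
    }
  }
  tau <- A <- B <- corr <- rep(NA_real_, npix)
  tau[mask] <- tau_hat; A[mask] <- A_hat; B[mask] <- B_hat
  corr[mask] <- corr_hat
  list(tau = tau, A = A, B = B, corr = corr, mask = mask,
       brightness = brightness)
}
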