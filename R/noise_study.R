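## How many images does a lifetime estimate need? Simulate a pool of
## noisy decay images, estimate lifetimes from the first n, and measure
## the mean absolute error against the 200-image estimate taken as ground
## truth.

#' Lifetime estimation error versus number of averaged images
#'
#' For each noise model a pool of `max(n_list)` noisy images is drawn
#' once; for every `n` in `n_list` the first `n` images are averaged and
#' per-pixel lifetimes estimated with each estimator. The estimate at
#' `n = max(n_list)` (200 by convention) on the same pool defines the
#' ground truth, so its own MAE is zero by construction. MAE is reported
#' over all fitted pixels and over the top 10% brightest.
#'
#' @param tau_map Matrix of true lifetimes (ns).
#' @param u IRF trace.
#' @param n_list Image counts evaluated; must contain its own maximum
#'   ground-truth count (200 by default usage).
#' @param noise_models Subset of `c("gaussian", "poisson")`.
#' @param estimators Subset of `c("ls", "poisson")` (Gaussian
#'   least-squares vs Poisson maximum likelihood).
#' @param photons_per_pixel Expected decay photons per pixel per image
#'   (scalar or matrix matching `tau_map`; real specimens have a wide
#'   brightness range, so pass a map when the bright-pixel subset should
#'   mean something).
#' @param offset Constant background (counts/bin).
#' @param read_noise Additive Gaussian measurement noise per bin per image
#'   (sd, counts): the analog detection chain's noise floor, which
#'   dominates dim pixels and is not captured by either counting noise
#'   model.
#' @param threshold_pct Brightness percentile below which pixels are not
#'   fitted.
#' @param seed Integer seed.
#' @param dt Bin width, ns.
#' @return `data.frame` with columns `n`, `noise_model`, `estimator`,
#'   `scope` (`"all"` / `"top10"`), `mae` (ns).
#' @export
lifetime_noise_study <- function(tau_map, u,
                                 n_list = c(1, 5, 20, 50, 200),
                                 noise_models = c("gaussian", "poisson"),
                                 estimators = c("ls", "poisson"),
                                 photons_per_pixel = 200, offset = 0.5,
                                 read_noise = 3, threshold_pct = 50,
                                 seed = 1L, dt = 0.3125) {
  n_list <- sort(unique(as.integer(n_list)))
  n_max <- max(n_list)
  u <- u / sum(u)
  rows <- list()
  for (nm in noise_models) {
    pool <- simulate_decay_images(tau_map, u, photons_per_pixel, n_max,
                                  noise_model = nm, offset = offset,
                                  read_noise = read_noise,
                                  seed = seed + match(nm, noise_models))
    csum <- array(0, dim = dim(pool$images)[1:2])
    means <- vector("list", length(n_list))
    k <- 0L
    for (i in seq_len(n_max)) {
      csum <- csum + pool$images[, , i]
      if (i %in% n_list) {
        k <- k + 1L
        means[[k]] <- csum / i
      }
    }
    for (est in estimators) {
      fits <- lapply(means, function(Y) {
        Y <- pmax(Y, 0) # Gaussian draws can go negative at low counts
        fit_lifetime_image(Y, u, method = est,
                           threshold_pct = threshold_pct, dt = dt)
      })
      ref <- fits[[length(n_list)]]
      bright <- ref$brightness
      top <- bright >= quantile(bright, 0.9)
      for (k in seq_along(n_list)) {
        err <- abs(fits[[k]]$tau - ref$tau)
        for (scope in c("all", "top10")) {
          sel <- if (scope == "all") !is.na(err) else top & !is.na(err)
          rows[[length(rows) + 1L]] <- data.frame(
            n = n_list[k], noise_model = nm, estimator = est,
            scope = scope, mae = mean(err[sel]))
        }
      }
    }
  }
  do.call(rbind, rows)
}
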