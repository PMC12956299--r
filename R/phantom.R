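## Ground-truth specimens for the simulator: per-path brightness maps, a
## lifetime map and labelled object masks.

#' Construct a phantom specimen
#'
#' @param brightness_maps List of matrices (one per excitation path), mean
#'   detected photons per laser pulse per pixel; all non-negative and of
#'   identical dimension.
#' @param tau_map Matrix of fluorescence lifetimes (ns), same dimension;
#'   must be positive wherever any path is bright.
#' @param labels Integer matrix of ground-truth object ids (0 background).
#' @return Object of class `phantom`.
#' @export
phantom <- function(brightness_maps, tau_map, labels = NULL) {
  if (!is.list(brightness_maps) || !length(brightness_maps))
    stop_invalid("`brightness_maps` must be a non-empty list of matrices")
  dims <- dim(brightness_maps[[1]])
  for (b in brightness_maps) {
    if (!identical(dim(b), dims)) stop_invalid("brightness maps differ in size")
    if (any(b < 0)) stop_invalid("brightness must be non-negative")
  }
  if (!identical(dim(tau_map), dims))
    stop_invalid("`tau_map` dimension mismatch")
  bright_any <- Reduce(`+`, brightness_maps) > 0
  if (any(tau_map[bright_any] <= 0))
    stop_invalid("`tau_map` must be positive where brightness > 0")
  if (is.null(labels)) labels <- matrix(0L, dims[1], dims[2])
  structure(list(brightness_maps = brightness_maps, tau_map = tau_map,
                 labels = labels),
            class = "phantom")
}

#' Generate a reproducible synthetic phantom
#'
#' Places `n_objects` disjoint objects (beads: small discs; cells: soft
#' discs; vessels: thick line segments) on a dark background, assigns each
#' to one excitation path in round-robin order and alternates objects
#' between (at least) two lifetime classes.
#'
#' @param kind One of `"beads"`, `"cells"`, `"vessels"`.
#' @param shape `(lines, pixels)` image size.
#' @param n_objects Number of objects; 0 yields a uniform background.
#' @param seed Integer seed (reproducible down to the bit).
#' @param n_paths Number of excitation paths (brightness maps).
#' @param brightness Peak object brightness, photons/pulse.
#' @param background Background brightness added to every path.
#' @param taus Lifetime classes (ns), cycled over objects; also sets the
#'   background lifetime (`taus[1]`).
#' @return A [phantom()].
#' @export
make_phantom <- function(kind = c("beads", "cells", "vessels"),
                         shape = c(64L, 64L), n_objects = 8L, seed = 1L,
                         n_paths = 4L, brightness = 5, background = 0,
                         taus = c(1.5, 3.0)) {
  kind <- match.arg(kind)
  nr <- shape[1]; nc <- shape[2]
  labels <- matrix(0L, nr, nc)
  maps <- replicate(n_paths, matrix(background, nr, nc), simplify = FALSE)
  tau_map <- matrix(taus[1], nr, nc)
  if (n_objects > 0) with_seed(seed, {
    radius <- switch(kind, beads = max(1, round(min(nr, nc) / 24)),
                     cells = max(2, round(min(nr, nc) / 12)),
                     vessels = max(1, round(min(nr, nc) / 32)))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    placed <- 0L; tries <- 0L
    while (placed < n_objects && tries < 500L * n_objects) {
      tries <- tries + 1L
      cy <- runif(1, 1 + radius, nr - radius)
      cx <- runif(1, 1 + radius, nc - radius)
      mask <- switch(kind,
        beads = ,
        cells = (rows - cy)^2 + (cols - cx)^2 <= radius^2,
        vessels = {
          ang <- runif(1, 0, pi)
          len <- runif(1, min(nr, nc) / 4, min(nr, nc) / 2)
          d_par <- (rows - cy) * cos(ang) + (cols - cx) * sin(ang)
          d_perp <- -(rows - cy) * sin(ang) + (cols - cx) * cos(ang)
          abs(d_par) <= len / 2 & abs(d_perp) <= radius
        })
      if (!any(mask) || any(labels[mask] != 0L)) next
      placed <- placed + 1L
      labels[mask] <- placed
      path <- ((placed - 1L) %% n_paths) + 1L
      amp <- if (kind == "cells")
        brightness * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * (radius / 1.5)^2))
      else matrix(brightness, nr, nc)
      maps[[path]][mask] <- maps[[path]][mask] + amp[mask]
      tau_map[mask] <- taus[((placed - 1L) %% length(taus)) + 1L]
    }
    if (placed < n_objects)
      warning("could only place ", placed, " of ", n_objects,
              " disjoint objects")
  })
  phantom(maps, tau_map, labels)
}

#' Single bright pixel phantom (point source)
#'
#' @param shape `(lines, pixels)` image size.
#' @param row,col Pixel coordinates of the source (1-based).
#' @param path Excitation path carrying the source (1-based).
#' @param brightness Photons per pulse at the source.
#' @param n_paths Number of paths.
#' @param tau Fluorescence lifetime at the source (ns).
#' @return A [phantom()].
#' @export
point_phantom <- function(shape, row, col, path = 1L, brightness = 20,
                          n_paths = 4L, tau = 0.5) {
  maps <- replicate(n_paths, matrix(0, shape[1], shape[2]), simplify = FALSE)
  maps[[path]][row, col] <- brightness
  tau_map <- matrix(tau, shape[1], shape[2])
  labels <- matrix(0L, shape[1], shape[2]); labels[row, col] <- 1L
  phantom(maps, tau_map, labels)
}
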