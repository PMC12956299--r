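## Rapid lifetime determination from four time gates, and the genetic
## algorithm that picks the gate positions so four-gate lifetimes best
## reproduce the full 40-bin fits.

#' A four-window time-gate gene
#'
#' Eight ordered bin indices `b1..b8` in `[0, n_bins - 1]` interpreted as
#' four inclusive windows `(b1, b2) .. (b7, b8)`, with
#' `b1 <= b2 < b3 <= b4 < b5 <= b6 < b7 <= b8`.
#'
#' @param bins Integer vector of 8 bin indices.
#' @param n_bins Total bins.
#' @return Object of class `gate_gene` with `bins` and `windows`
#'   (4 x 2 matrix).
#' @export
gate_gene <- function(bins, n_bins = 40L) {
  bins <- as.integer(bins)
  if (!gene_valid(bins, n_bins))
    stop_invalid("gene must satisfy b1<=b2<b3<=b4<b5<=b6<b7<=b8 within 0..",
                 n_bins - 1L)
  structure(list(bins = bins, windows = matrix(bins, 4L, 2L, byrow = TRUE)),
            class = "gate_gene")
}

gene_valid <- function(b, n_bins = 40L) {
  length(b) == 8L && all(b >= 0L) && all(b < n_bins) &&
    b[1] <= b[2] && b[2] < b[3] && b[3] <= b[4] && b[4] < b[5] &&
    b[5] <= b[6] && b[6] < b[7] && b[7] <= b[8]
}

#' Preprocess traces for four-gate estimation
#'
#' Circularly shifts each trace so the reference bin sits at bin 0 and
#' subtracts a constant baseline.
#'
#' @param x Trace vector, pixels x bins matrix, or [decay_stack()].
#' @param shift Reference bin moved to bin 0 (default 19).
#' @param baseline Constant baseline to subtract; `NULL` uses each
#'   trace's minimum.
#' @return Same shape as the input (matrix for stacks).
#' @export
fourgate_preprocess <- function(x, shift = 19L, baseline = NULL) {
  m <- if (inherits(x, "decay_stack")) x$cube else
    if (is.matrix(x)) x else matrix(x, 1L)
  nb <- ncol(m)
  idx <- ((seq_len(nb) - 1L + shift) %% nb) + 1L
  m <- m[, idx, drop = FALSE]
  base <- if (is.null(baseline)) apply(m, 1L, min) else baseline
  m <- m - base
  if (is.matrix(x) || inherits(x, "decay_stack")) m else drop(m)
}

## Mean of the model basis over each window of a gene; H is nbins x ntau
## (or a vector), returns 4 x ntau (or length-4).
window_means <- function(M, gene) {
  w <- gene$windows
  out <- vapply(1:4, function(g) {
    rows <- (w[g, 1]:w[g, 2]) + 1L
    if (is.matrix(M)) colMeans(M[rows, , drop = FALSE]) else mean(M[rows])
  }, if (is.matrix(M)) numeric(ncol(M)) else numeric(1))
  if (is.matrix(M)) t(matrix(out, ncol = 4L)) else as.numeric(out)
}

#' Four-gate lifetime of a single trace
#'
#' Observed gate intensities `Y_g` are means of the (preprocessed) trace
#' over each window's bins. The model intensities are the same window
#' means of the IRF-convolved mono-exponential, with the amplitude fitted
#' linearly per candidate `tau`; `tau` minimizes the residual sum of
#' squares by a 1-D bounded search with tolerance 1e-4.
#'
#' @param y Preprocessed trace (see [fourgate_preprocess()]).
#' @param gene A [gate_gene()].
#' @param u IRF trace, preprocessed the same way (normalized internally).
#' @param tau_range Search bounds, ns.
#' @param dt Bin width, ns.
#' @param tol Search tolerance on `tau`.
#' @return Lifetime (ns) with attribute `boundary` set when the search
#'   terminates at a bound.
#' @export
four_gate_lifetime <- function(y, gene, u, tau_range = c(0.3125, 12.5),
                               dt = 0.3125, tol = 1e-4) {
  stopifnot(inherits(gene, "gate_gene"))
  u <- pmax(u, 0); u <- u / sum(u)
  Yg <- window_means(if (is.matrix(y)) drop(y) else y, gene)
  rss <- function(tau) {
    Hg <- window_means(decay_basis(u, tau, dt), gene)
    denom <- sum(Hg^2)
    alpha <- if (denom > 0) max(0, sum(Yg * Hg) / denom) else 0
    sum((Yg - alpha * Hg)^2)
  }
  opt <- optimize(rss, tau_range, tol = tol)
  tau <- opt$minimum
  structure(tau, boundary = tau <= tau_range[1] + 10 * tol ||
              tau >= tau_range[2] - 10 * tol)
}

#' Genetic-algorithm configuration
#'
#' @param population Genes per generation.
#' @param generations Generations evolved.
#' @param elites Top genes carried over unchanged.
#' @param fitness_pixels Pixels used to score genes.
#' @param seed Seed fixing the pixel selection and the evolution.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 100L, generations = 100L, elites = 20L,
                      fitness_pixels = 120L, seed = 1L) {
  if (elites >= population) stop_invalid("`elites` must be < `population`")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 elites = as.integer(elites),
                 offspring = as.integer(population - elites),
                 fitness_pixels = as.integer(fitness_pixels),
                 seed = as.integer(seed)),
            class = "ga_config")
}

random_gene <- function(n_bins = 40L) {
  repeat {
    b <- sort(sample.int(n_bins, 8L, replace = TRUE) - 1L)
    if (gene_valid(b, n_bins)) return(b)
  }
}

mutate_gene <- function(b, n_bins = 40L, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    nb <- b
    pos <- sample.int(8L, 1L)
    nb[pos] <- nb[pos] + sample(c(-1L, 1L), 1L)
    if (gene_valid(nb, n_bins)) return(nb)
  }
  b # give up; caller dedupes
}

#' Optimize four-gate positions with a genetic algorithm
#'
#' Fitness of a gene is the Pearson correlation between its four-gate
#' lifetimes and the full 40-bin fit lifetimes over a fixed, seeded set of
#' bright pixels. Each generation the top `elites` genes survive
#' unchanged and the rest are offspring of a random elite with one bin
#' index shifted by +/-1; duplicates are removed. With elitism the best
#' fitness is non-decreasing.
#'
#' Inside the GA the per-pixel `tau` search runs on a shared fine lifetime
#' grid with parabolic refinement (numerically equivalent to the 1-D
#' bounded search of [four_gate_lifetime()] at far lower cost).
#'
#' @param stack A [decay_stack()] or pixels x bins matrix, already
#'   preprocessed by [fourgate_preprocess()].
#' @param u IRF trace, equally preprocessed.
#' @param config A [ga_config()].
#' @param tau_truth Optional full-fit lifetimes per pixel; computed with
#'   [fit_lifetime_image()] (LS) when missing.
#' @param tau_range Lifetime search bounds, ns.
#' @param dt Bin width, ns.
#' @param n_grid Lifetime grid size for the vectorized search.
#' @param threshold_pct Brightness percentile defining eligible pixels.
#' @return List: `best_gene` ([gate_gene()]), `best_fitness`, `history`
#'   (best fitness per generation), `pixels` (indices scored), `config`.
#' @export
ga_optimize_gates <- function(stack, u, config = ga_config(),
                              tau_truth = NULL, tau_range = c(0.3125, 12.5),
                              dt = 0.3125, n_grid = 200L,
                              threshold_pct = 50) {
  Y <- if (inherits(stack, "decay_stack")) stack$cube else as.matrix(stack)
  nb <- ncol(Y)
  u <- pmax(u, 0); u <- u / sum(u)
  if (is.null(tau_truth))
    tau_truth <- fit_lifetime_image(Y, u, method = "ls",
                                    threshold_pct = threshold_pct,
                                    tau_range = tau_range, dt = dt)$tau
  bright <- which(!is.na(tau_truth))
  if (length(bright) < config$fitness_pixels)
    stop_invalid("not enough pixels above threshold for fitness evaluation")
  grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = n_grid))
  H <- vapply(grid, function(tt) decay_basis(u, tt, dt), numeric(nb))
  lg <- log(grid); step <- lg[2] - lg[1]

  with_seed(config$seed, {
    pixels <- sort(sample(bright, config$fitness_pixels))
    Yp <- Y[pixels, , drop = FALSE]
    truth <- tau_truth[pixels]

    fitness_of <- function(bins) {
      gene <- gate_gene(bins, nb)
      Hg <- window_means(H, gene)          # 4 x n_grid
      Yg <- t(window_means(t(Yp), gene))   # pixels x 4
      denom <- colSums(Hg^2)
      A <- Yg %*% Hg                        # pixels x n_grid
      A[A < 0] <- 0
      rss <- rowSums(Yg^2) - sweep(A^2, 2L, pmax(denom, 1e-300), "/")
      gi <- max.col(-rss, ties.method = "first")
      tau <- grid[gi]
      inter <- which(gi > 1L & gi < n_grid)
      if (length(inter)) {
        y1 <- rss[cbind(inter, gi[inter] - 1L)]
        y2 <- rss[cbind(inter, gi[inter])]
        y3 <- rss[cbind(inter, gi[inter] + 1L)]
        dd <- y1 - 2 * y2 + y3
        ok <- dd > 0
        tau[inter[ok]] <- exp(lg[gi[inter[ok]]] +
                                0.5 * step * ((y1 - y3)[ok] / dd[ok]))
      }
      if (sd(tau) == 0) return(-1)
      cor(tau, truth)
    }

    cache <- new.env(parent = emptyenv())
    score <- function(bins) {
      key <- paste(bins, collapse = ",")
      if (is.null(cache[[key]])) cache[[key]] <- fitness_of(bins)
      cache[[key]]
    }

    pop <- replicate(config$population, random_gene(nb), simplify = FALSE)
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      fits <- vapply(pop, score, numeric(1))
      ord <- order(fits, decreasing = TRUE)
      pop <- pop[ord]; fits <- fits[ord]
      history[gen] <- fits[1]
      if (gen == config$generations) break
      elites <- pop[seq_len(config$elites)]
      children <- list()
      seen <- vapply(elites, paste, character(1), collapse = ",")
      tries <- 0L
      while (length(children) < config$offspring && tries < 50L * config$offspring) {
        tries <- tries + 1L
        parent <- elites[[sample.int(config$elites, 1L)]]
        child <- mutate_gene(parent, nb)
        key <- paste(child, collapse = ",")
        if (key %in% seen) next # duplicates removed to maintain diversity
        seen <- c(seen, key)
        children[[length(children) + 1L]] <- child
      }
      while (length(children) < config$offspring)
        children[[length(children) + 1L]] <- random_gene(nb)
      pop <- c(elites, children)
    }
    list(best_gene = gate_gene(pop[[1]], nb), best_fitness = history[length(history)],
         history = history, pixels = pixels, config = config)
  })
}
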