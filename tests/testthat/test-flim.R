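test_that("windowed acquisitions assemble into a 40-bin stack", {
  set.seed(41)
  full <- matrix(runif(5 * 40), 5, 40)
  acqs <- lapply(0:9, function(w)
    list(bins = (4 * w):(4 * w + 3), data = full[, 4 * w + 1:4]))
  st <- assemble_decay_stack(acqs)
  expect_equal(st$cube, full)
  # permuted acquisition order: same stack
  st2 <- assemble_decay_stack(acqs[c(3, 1, 10, 2, 9, 4, 8, 5, 7, 6)])
  expect_equal(st2$cube, full)
  expect_error(assemble_decay_stack(acqs[-4]), "missing")
  dup <- acqs; dup[[2]]$bins <- 0:3
  expect_error(assemble_decay_stack(dup), "overlap")
})

test_that("the convolution model matches its scalar triple-period oracle", {
  set.seed(42)
  for (i in 1:8) {
    u <- runif(40); u <- u / sum(u)
    A <- runif(1, 1, 100); B <- runif(1, 0, 5); tau <- runif(1, 0.4, 6)
    expect_equal(convolve_model(u, A, B, tau),
                 oracle_convolve_model(u, A, B, tau), tolerance = 1e-12)
  }
  u <- ringing_irf()
  # A = 0: constant trace B (unit-sum IRF)
  expect_equal(convolve_model(u, 0, 3.5, 1.0), rep(3.5, 40))
  # delta IRF: exponential plus wrap term
  delta <- c(1, numeric(39))
  got <- convolve_model(delta, 1, 0, 2.5)
  k <- 0:39
  wrap <- exp(-k * 0.3125 / 2.5) + exp(-(k + 40) * 0.3125 / 2.5) +
    exp(-(k + 80) * 0.3125 / 2.5)
  expect_equal(got, wrap, tolerance = 1e-12)
  # cyclic shift of the IRF cyclically shifts the model
  m <- 7L
  ush <- u[((0:39 - m) %% 40) + 1]
  g1 <- convolve_model(u, 2, 0, 1.8)
  g2 <- convolve_model(ush, 2, 0, 1.8)
  expect_equal(g2, g1[((0:39 - m) %% 40) + 1], tolerance = 1e-10)
  expect_error(convolve_model(u, 1, 0, -1), "positive")
})

test_that("least-squares fitting recovers parameters and finds the global minimum", {
  u <- ringing_irf()
  y <- convolve_model(u, 100, 2, 2.0)
  f <- fit_lifetime_ls(y, u)
  expect_lt(abs(f$tau - 2.0), 0.02)
  expect_equal(f$A, 100, tolerance = 1e-3)
  expect_equal(f$B, 2, tolerance = 1e-3)
  expect_gt(f$corr, 0.9999)
  expect_true(f$converged)
  # residual at the optimum beats a dense grid
  dense <- vapply(seq(0.35, 12, length.out = 400), function(tt)
    mux2p:::ls_amplitudes(y, decay_basis_(u, tt), 1)$rss, numeric(1))
  expect_lte(f$rss, min(dense) + 1e-9)
  # constant trace: amplitude zero, flagged unidentifiable
  g <- fit_lifetime_ls(rep(4, 40), u)
  expect_equal(g$A, 0, tolerance = 1e-9)
  expect_false(g$converged)
})

test_that("Poisson MLE agrees with truth when noiseless and with LS at high counts", {
  u <- ringing_irf()
  lam <- convolve_model(u, 80, 1.5, 2.6)
  f <- fit_lifetime_poisson(lam, u)
  expect_lt(abs(f$tau - 2.6) / 2.6, 0.005)
  set.seed(43)
  rel <- replicate(10, {
    tau <- runif(1, 1, 4)
    A <- 2e4 / sum(decay_basis_(u, tau))
    y <- rpois(40, convolve_model(u, A, 3, tau))
    fl <- fit_lifetime_ls(y, u); fp <- fit_lifetime_poisson(y, u)
    abs(fl$tau - fp$tau) / fl$tau
  })
  expect_lt(median(rel), 0.01)
})

test_that("image-level fitting matches per-pixel fits and applies the threshold", {
  u <- ringing_irf()
  set.seed(44)
  taus <- runif(12, 1, 4)
  Y <- t(vapply(taus, function(tt)
    convolve_model(u, 50, 1, tt), numeric(40))) + 0.3
  res <- fit_lifetime_image(Y, u, threshold_pct = 0, n_grid = 200)
  scalar <- vapply(seq_len(12), function(p) fit_lifetime_ls(Y[p, ], u)$tau,
                   numeric(1))
  expect_equal(res$tau, scalar, tolerance = 0.01)
  # dim pixels skipped under a percentile threshold
  Y2 <- rbind(Y, matrix(0.1, 12, 40))
  res2 <- fit_lifetime_image(Y2, u, threshold_pct = 50)
  expect_true(all(is.na(res2$tau[13:24])))
  expect_true(all(!is.na(res2$tau[1:12])))
})

test_that("phasor coordinates behave as the discrete Fourier construction", {
  u <- ringing_irf()
  # trace identical to the IRF: C = 1, phi = 0, tau = 0
  self <- phasor_lifetime(u, u)
  expect_equal(self$g, 1, tolerance = 1e-12)
  expect_equal(self$s, 0, tolerance = 1e-12)
  expect_equal(self$tau, 0, tolerance = 1e-12)
  # IRF self-reference holds for arbitrary IRFs
  set.seed(45)
  for (i in 1:5) {
    ur <- runif(40)
    expect_equal(phasor_lifetime(ur, ur)$tau, 0, tolerance = 1e-10)
  }
  # dense sampling, delta IRF: analytic single-exponential phasor limit
  nb <- 4000L; dt <- 12.5 / nb
  delta <- c(1, numeric(nb - 1))
  tau <- 1.0
  y <- exp(-(0:(nb - 1)) * dt / tau)
  ph <- phasor_lifetime(y, delta, dt = dt)
  omega_tau <- 2 * pi / 12.5 * tau
  expect_equal(ph$g, 1 / (1 + omega_tau^2), tolerance = 5e-3)
  expect_equal(ph$s, omega_tau / (1 + omega_tau^2), tolerance = 5e-3)
  expect_equal(ph$tau, tau, tolerance = 0.02)
  # constant trace is undefined and flagged
  expect_true(phasor_lifetime(rep(2, 40), u)$undefined)
})

test_that("phasor lifetimes rank-agree with full fits on noiseless stacks", {
  u <- ringing_irf()
  set.seed(46)
  taus <- runif(40, 0.8, 4)
  Y <- t(vapply(taus, function(tt) convolve_model(u, 60, 0.5, tt),
                numeric(40)))
  tau_ls <- fit_lifetime_image(Y, u, threshold_pct = 0)$tau
  tau_ph <- phasor_image(Y, u)
  expect_gte(cor(tau_ph, tau_ls, method = "spearman"), 0.99)
})
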