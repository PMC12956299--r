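test_that("photon kernel has the configured width, ringing and polarity", {
  k <- make_photon_kernel(fwhm_ns = 1.875, ring_amp = 0.25)
  expect_equal(k$kernel[k$trough_index], -1, tolerance = 1e-9)
  # 1.875 ns at 3.2 GS/s = 6 samples +/- 1
  expect_lt(abs(k$measured_fwhm_ns / 0.3125 - 6), 1)

  pure <- make_photon_kernel(fwhm_ns = 1.875, ring_amp = 0)
  expect_true(all(pure$kernel <= 0))

  # trough-to-first-positive-peak delay equals the configured value
  for (d in c(1.5, 2.0, 3.0)) {
    kk <- make_photon_kernel(fwhm_ns = 1.0, ring_amp = 0.3,
                             peak_delay_ns = d)
    post <- kk$kernel[kk$trough_index:length(kk$kernel)]
    peak <- which.max(post) - 1L
    expect_lt(abs(peak * 0.3125 - d), 0.3125 + 1e-9)
  }
  expect_error(make_photon_kernel(fwhm_ns = 0.3), "2 sample")
})

test_that("phantoms are reproducible with disjoint labelled objects", {
  p1 <- make_phantom("beads", c(32L, 32L), n_objects = 6, seed = 3)
  p2 <- make_phantom("beads", c(32L, 32L), n_objects = 6, seed = 3)
  expect_identical(p1, p2)
  expect_identical(sort(unique(as.vector(p1$labels))), 0:6)
  # objects disjoint by construction: each labelled pixel has one id
  expect_equal(sum(p1$labels > 0),
               sum(table(p1$labels[p1$labels > 0])))
  expect_true(all(p1$tau_map > 0))
  expect_gte(length(unique(p1$tau_map[p1$labels > 0])), 2)

  flat <- make_phantom("cells", c(16L, 16L), n_objects = 0, seed = 1,
                       background = 2)
  expect_true(all(flat$brightness_maps[[1]] == 2))
  expect_true(all(flat$labels == 0))
})

test_that("simulated streams have the configured clock and sync structure", {
  cfg <- test_config(lines = 8L, pixels = 8L)
  ph <- make_phantom("beads", c(8L, 8L), n_objects = 2, seed = 1,
                     brightness = 5)
  st <- simulate_pmt_stream(ph, cfg, seed = 1, kernel = test_kernel())
  expect_true(all(diff(st$laser_clock) == cfg$samples_per_pulse))
  half_period <- cfg$sample_rate / (2 * cfg$resonant_freq)
  expect_true(all(abs(diff(st$hsync1) - half_period) <= 1))
  expect_true(all(abs(diff(st$hsync2) - half_period) <= 1))
  # free-running scanners: same rate, different phase
  expect_false(st$hsync1[1] == st$hsync2[1])
  expect_true(all(st$laser_clock <= length(st$waveform)))
})

test_that("zero brightness yields pure baseline noise", {
  cfg <- test_config(lines = 8L, pixels = 8L, noise_sd = 0.05)
  ph <- phantom(replicate(4, matrix(0, 8, 8), simplify = FALSE),
                matrix(1, 8, 8))
  st <- simulate_pmt_stream(ph, cfg, seed = 2, kernel = test_kernel())
  expect_lt(abs(mean(st$waveform)), 3 * 0.05 / sqrt(length(st$waveform)) + 1e-4)
  cnt <- integrate_gates(suppressWarnings(slice_pulse_records(st)),
                         default_gate_set(), clip = FALSE)
  expect_lt(abs(mean(cnt$values)), 0.05)
})

test_that("a one-path phantom lands >= 99% of its energy in its own channel", {
  cfg <- test_config(lines = 16L, pixels = 16L, noise_sd = 0)
  for (path in c(1L, 3L)) {
    ph <- point_phantom(c(16L, 16L), 8, 8, path = path, brightness = 40,
                        tau = 0.4)
    # pad the point with a block so more pulses carry signal
    ph$brightness_maps[[path]][6:10, 6:10] <- 40
    st <- simulate_pmt_stream(ph, cfg, seed = 3, kernel = test_kernel())
    cnt <- integrate_gates(suppressWarnings(slice_pulse_records(st)),
                           default_gate_set(), clip = FALSE)
    tot <- colSums(cnt$values)
    expect_gte(tot[path] / sum(tot), 0.99)
  }
})

test_that("total detected photon energy matches Poisson expectations", {
  cfg <- test_config(lines = 16L, pixels = 16L, noise_sd = 0)
  ph <- make_phantom("beads", c(16L, 16L), n_objects = 3, seed = 4,
                     brightness = 10, taus = c(0.4, 0.6))
  st <- simulate_pmt_stream(ph, cfg, seed = 5, kernel = test_kernel())
  area <- -sum(test_kernel()$kernel) # energy deposited per photon
  n_est <- sum(-st$waveform) / area
  # expected photons: per-path sum of brightness x pulse visits
  mu <- sum(vapply(seq_len(4), function(path) {
    sw <- if (path %% 2 == 1) st$hsync1 else st$hsync2
    phs <- cfg$scanner_phases[if (path %% 2 == 1) 1 else 2]
    tp <- (st$laser_clock - 1) / cfg$sample_rate
    row <- mux2p:::address_rows(st$laser_clock, sw, st$vsync,
                                cfg$lines_per_frame)
    col <- mux2p:::position_to_column(
      cos(2 * pi * cfg$resonant_freq * tp + phs),
      cfg$fill_fraction, cfg$pixels_per_line)
    ok <- !is.na(row) & !is.na(col)
    sum(ph$brightness_maps[[path]][cbind(row[ok], col[ok])])
  }, numeric(1)))
  expect_lt(abs(n_est - mu), 4 * sqrt(mu))
})

test_that("decay stacks follow the convolution model and Poisson statistics", {
  # noiseless, delta IRF: exponential plus periodic wrap (scalar oracle)
  delta <- c(1, numeric(39))
  tau_map <- matrix(2.5, 1, 1)
  st <- simulate_decay_stack(tau_map, delta, photons_per_pixel = 100,
                             n_images = Inf)
  h <- oracle_convolve_model(delta, 1, 0, 2.5)
  expect_equal(as.numeric(st$cube), 100 * h / sum(h) + 0.5,
               tolerance = 1e-9)

  # Poisson: per-bin variance across images ~ lambda
  sim <- simulate_decay_images(matrix(2, 1, 1), ringing_irf(),
                               photons_per_pixel = 400, n_images = 400,
                               noise_model = "poisson", seed = 6)
  v_emp <- apply(sim$images[1, , ], 1, var)
  lam <- sim$lambda[1, ]
  expect_lt(median(abs(v_emp - lam) / lam), 0.25)

  # constant tau: identical expected traces across pixels
  st2 <- simulate_decay_stack(matrix(1.7, 3, 2), ringing_irf(),
                              n_images = Inf)
  expect_equal(st2$cube[1, ], st2$cube[6, ])

  expect_error(simulate_decay_images(matrix(1, 1, 1), ringing_irf(),
                                     noise_model = "weird"))
})

test_that("calcium traces expose their ground-truth baseline", {
  quiet <- simulate_calcium_traces(3, duration_s = 60, fs = 10,
                                   transient_rate = 0, seed = 1,
                                   noise_sd = 0.01)
  expect_lt(max(abs(quiet$traces - quiet$baseline)), 0.06)

  act <- simulate_calcium_traces(5, duration_s = 120, fs = 10,
                                 transient_rate = 0.2, seed = 2)
  expect_gte(mean(act$traces), mean(act$baseline) - 1e-6)
  act2 <- simulate_calcium_traces(5, duration_s = 120, fs = 10,
                                  transient_rate = 0.2, seed = 2)
  expect_identical(act, act2)
})
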