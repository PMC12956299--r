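test_that("pulse records tile the stream with the documented overlap", {
  cfg <- test_config(lines = 8L, pixels = 8L)
  ph <- make_phantom("beads", c(8L, 8L), n_objects = 2, seed = 1)
  st <- simulate_pmt_stream(ph, cfg, seed = 1, kernel = test_kernel())
  rec <- suppressWarnings(slice_pulse_records(st, record_len = 48L))
  # no pulse lost beyond the boundary drop
  expect_gte(nrow(rec$records), length(st$laser_clock) - 2L)
  expect_identical(rec$parity, (rec$pulse_index - 1L) %% 2L)
  # overlap of 8 samples: the tail of record k equals the head of the
  # next pulse's span on the same waveform
  expect_equal(rec$records[1, 41:48],
               st$waveform[st$laser_clock[2] + 0:7])
  # record_len = one period: zero overlap, records abut exactly
  rec40 <- suppressWarnings(slice_pulse_records(st, record_len = 40L))
  expect_equal(as.vector(t(rec40$records[1:10, ])),
               st$waveform[seq_len(400)])
})

test_that("gate integration equals the per-sample scalar reference", {
  gates <- gate_set(list(c(5, 7), c(10, 12), c(15, 17), c(20, 22)))
  # hand-computable record
  wave <- -(1:100)
  rec <- suppressWarnings(
    slice_pulse_records(list(waveform = wave, laser_clock = c(1L, 41L)),
                        record_len = 48L))
  cnt <- integrate_gates(rec, gates)
  expect_equal(cnt$values[1, ], c(6 + 7 + 8, 11 + 12 + 13, 16 + 17 + 18,
                                  21 + 22 + 23))
  # zero record -> zero counts
  z <- suppressWarnings(
    slice_pulse_records(list(waveform = numeric(60), laser_clock = 1L), 48L))
  expect_equal(as.vector(integrate_gates(z, gates)$values), rep(0, 4))
  # random records against the brute-force oracle
  set.seed(11)
  fake <- list(waveform = rnorm(48 * 500, 0, 100),
               laser_clock = seq(1L, by = 48L, length.out = 500L))
  recs <- slice_pulse_records(fake, 48L)
  for (base in c(0, 5)) {
    got <- integrate_gates(recs, gates, baseline = base)$values
    want <- oracle_gate_sums(recs$records, gates, baseline = base)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("gate integration is linear before clipping and saturates after", {
  gates <- default_gate_set()
  set.seed(12)
  mk <- function(w) suppressWarnings(slice_pulse_records(
    list(waveform = w, laser_clock = seq(1L, by = 40L, length.out = 20L)),
    48L))
  w1 <- rnorm(900); w2 <- rnorm(900)
  g <- function(w) integrate_gates(mk(w), gates, clip = FALSE)$values
  expect_equal(g(w1 + w2), g(w1) + g(w2), tolerance = 1e-10)
  # saturation at the 16-bit ceiling
  big <- integrate_gates(mk(rep(-1e5, 900)), gates, clip = TRUE)$values
  expect_true(all(big == 65535))
  neg <- integrate_gates(mk(rep(1e5, 900)), gates, clip = TRUE)$values
  expect_true(all(neg == 0))
})

test_that("gate sets validate their windows", {
  expect_error(gate_set(list(c(-1, 5), c(10, 12), c(15, 17), c(20, 22))),
               "0 <= start")
  expect_error(gate_set(list(c(5, 50), c(10, 12), c(15, 17), c(20, 22))),
               "0 <= start")
  expect_warning(gate_set(list(c(0, 10), c(5, 12), c(15, 17), c(20, 22))),
                 "overlap")
})

test_that("pulse accumulation sums groups and conserves totals", {
  set.seed(13)
  vals <- matrix(runif(4 * 40, 0, 100), 40, 4)
  cnt <- channel_counts(vals, clock = seq(1L, by = 40L, length.out = 40L))
  expect_identical(accumulate_pulses(cnt, 1), cnt)
  a4 <- accumulate_pulses(cnt, 4)
  expect_equal(nrow(a4$values), 10L)
  expect_equal(colSums(a4$values), colSums(vals))
  expect_equal(a4$values[1, ], colSums(vals[1:4, ]))
  expect_identical(a4$accumulation, 4L)
  # trailing remainder dropped with warning
  cnt2 <- channel_counts(vals[1:38, ])
  expect_warning(a2 <- accumulate_pulses(cnt2, 4), "trailing")
  expect_equal(colSums(a2$values), colSums(vals[1:36, ]))
  expect_error(accumulate_pulses(cnt, 3), "1, 2 or 4")
})

test_that("photon events are detected, aligned and characterized", {
  k <- test_kernel()
  n <- 4000L
  flat <- rnorm(n, 0, 1e-4)
  expect_equal(nrow(detect_photon_events(flat, -0.5)), 0L)

  inject <- function(w, at, kern = k, amp = 1) {
    idx <- at + seq_along(kern$kernel) - kern$trough_index
    ok <- idx >= 1 & idx <= length(w)
    w[idx[ok]] <- w[idx[ok]] + amp * kern$kernel[ok]
    w
  }
  one <- inject(numeric(n), 500L)
  ev <- detect_photon_events(one, -0.5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$trough_index, 500L)
  expect_lt(abs(ev$fwhm_ns - 0.9), 0.3125)

  two <- inject(inject(numeric(n), 500L), 700L)
  expect_equal(nrow(detect_photon_events(two, -0.5)), 2L)
})

test_that("event statistics capture jitter correlation and the ringing lag", {
  kr <- make_photon_kernel(fwhm_ns = 1.0, ring_amp = 0.3, peak_delay_ns = 2.0)
  n <- 60000L
  w <- numeric(n)
  set.seed(14)
  onsets <- cumsum(200L + sample(0:30, 120, replace = TRUE))
  for (at in onsets) {
    idx <- at + seq_along(kr$kernel) - kr$trough_index
    ok <- idx >= 1 & idx <= n
    w[idx[ok]] <- w[idx[ok]] + kr$kernel[ok]
  }
  ev <- detect_photon_events(w, -0.5)
  st <- photon_event_stats(ev, waveform = w)
  expect_equal(st$n_events, length(onsets))
  # onset-only jitter: trough and ringing peak shift together
  expect_gt(st$trough_peak_corr, 0.999)
  # identical pulses: FWHM is a point mass
  expect_lt(diff(range(st$fwhm_ns)), 1e-6)
  # configured trough-to-peak delay recovered
  expect_lt(abs(st$median_peak_lag * 0.3125 - 2.0), 0.5)
  expect_equal(nrow(st$alignment), length(onsets))
  # fewer than two events: correlation reported missing
  expect_true(is.na(photon_event_stats(ev[1, ])$trough_peak_corr))
})
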