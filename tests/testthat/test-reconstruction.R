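# Build a raw image directly (no simulator) from a spatial intensity
# profile: forward and backward lines sample the same scene through the
# cosine sweep, with an optional injected bidirectional misalignment.
synthetic_raw_image <- function(profile_fun, n_lines = 16L, n_pulses = 128L,
                                fill = 0.9, offset_px = 0,
                                n_out = 64L) {
  s <- (seq_len(n_pulses) - 0.5) / n_pulses
  x <- cos(pi * s)
  geom <- frame_geometry(n_lines, n_pulses, n_out, fill_fraction = fill)
  pix <- phase <- matrix(0, n_lines, n_pulses)
  dir <- rep(c(1L, -1L), length.out = n_lines)
  # offset in output-pixel units -> position units
  dx <- offset_px * 2 * fill / n_out
  for (l in seq_len(n_lines)) {
    shift <- if (dir[l] == 1L) 0 else dx
    pix[l, ] <- profile_fun(x + shift)
    phase[l, ] <- s
  }
  structure(list(pixels = pix, phase = phase, direction = dir,
                 channel = 1L, frame = 1L, geometry = geom),
            class = "raw_image")
}

test_that("constant counts reconstruct to a constant image", {
  img <- synthetic_raw_image(function(x) rep(5, length(x)))
  out <- desinusoid(img)
  expect_true(all(abs(out$pixels - 5) < 1e-12))
})

test_that("bidirectional offset estimation recovers injected shifts", {
  profile <- function(x) exp(-((x - 0.2) / 0.15)^2) + 0.5 * (x < -0.4)
  zero <- synthetic_raw_image(profile, offset_px = 0)
  expect_lt(abs(as.numeric(estimate_bidirectional_offset(zero))), 0.35)

  # the synthetic image shifts in position; convert a 3-output-pixel shift
  # into the pulse-domain estimate by desinusoiding first? The estimator
  # works on the raw (time-domain) image, so inject the shift there.
  shift_lines <- function(img, s) {
    for (l in which(img$direction == -1L))
      img$pixels[l, ] <- approx(seq_len(ncol(img$pixels)), img$pixels[l, ],
                                xout = seq_len(ncol(img$pixels)) - s,
                                rule = 2)$y
    img
  }
  base <- synthetic_raw_image(profile)
  for (s in c(3, -4)) {
    est <- as.numeric(estimate_bidirectional_offset(shift_lines(base, s)))
    expect_lt(abs(est - s), 0.35)
  }
  # shift equivariance
  e0 <- as.numeric(estimate_bidirectional_offset(base))
  e5 <- as.numeric(estimate_bidirectional_offset(shift_lines(base, 5)))
  expect_lt(abs((e5 - e0) - 5), 0.5)
  # applying the estimated offset re-aligns the lines
  sh <- shift_lines(base, 3)
  fixed <- apply_bidirectional_offset(
    sh, as.numeric(estimate_bidirectional_offset(sh)))
  expect_lt(abs(as.numeric(estimate_bidirectional_offset(fixed))), 0.5)
  # featureless image: zero shift, flagged
  flat <- synthetic_raw_image(function(x) rep(1, length(x)))
  e <- estimate_bidirectional_offset(flat)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "low_confidence"))
})

test_that("desinusoiding uniformizes bar spacing and preserves order", {
  # bars equally spaced in SPACE, imaged through the sinusoidal sweep
  bar_period <- 0.225 # position units; 8 output pixels at fill 0.9, 64 px
  profile <- function(x) as.numeric((x %% bar_period) < 0.05)
  img <- synthetic_raw_image(profile, n_lines = 2L, n_pulses = 512L,
                             n_out = 64L)
  out <- desinusoid(img)$pixels[1, ]
  centers <- which(diff(c(0, out > 0.5)) == 1)
  gaps <- diff(centers)
  expect_true(all(abs(gaps - mean(gaps)) <= 0.5 + 1e-9))

  # monotone: a spatial ramp stays a monotone pixel ramp
  ramp <- synthetic_raw_image(function(x) x, n_lines = 1L)
  expect_true(all(diff(desinusoid(ramp)$pixels[1, ]) < 0))

  # spatial integral conserved within interpolation tolerance
  smooth <- synthetic_raw_image(function(x) 2 + sin(3 * x) + 0.5 * x^2,
                                n_lines = 1L, n_pulses = 256L)
  x_in <- cos(pi * smooth$phase[1, ])
  keep <- abs(x_in) <= 0.9
  ordx <- order(x_in[keep])
  xi <- x_in[keep][ordx]; yi <- smooth$pixels[1, keep][ordx]
  integral_in <- sum(diff(xi) * (head(yi, -1) + tail(yi, -1)) / 2)
  out2 <- desinusoid(smooth)$pixels[1, ]
  integral_out <- sum(out2) * (2 * 0.9 / length(out2))
  expect_lt(abs(integral_out - abs(integral_in)) / abs(integral_in), 0.01)
})

test_that("frames assemble against the correct scanner sync", {
  cfg <- test_config()
  ph <- make_phantom("beads", c(24L, 24L), n_objects = 6, seed = 5,
                     brightness = 25, taus = c(0.3, 0.5))
  st <- simulate_pmt_stream(ph, cfg, seed = 21, kernel = test_kernel())
  cnt <- integrate_gates(suppressWarnings(slice_pulse_records(st)),
                         default_gate_set())
  geom1 <- geometry_from_config(
    cfg, first_line_forward = first_line_direction(st, 1, 1))
  geom2 <- geometry_from_config(
    cfg, first_line_forward = first_line_direction(st, 2, 1))
  right <- desinusoid(assemble_frame(cnt, st$hsync2, st$vsync, geom2, 2))
  wrong <- desinusoid(assemble_frame(cnt, st$hsync1, st$vsync, geom1, 2))
  truth <- as.vector(ph$brightness_maps[[2]])
  expect_gt(cor(as.vector(right$pixels), truth), 0.9)
  expect_lt(abs(cor(as.vector(wrong$pixels), truth)), 0.2)
  # insufficient syncs -> partial-frame error
  expect_error(assemble_frame(cnt, st$hsync1[1:5], st$vsync, geom1, 1),
               "partial")
})

test_that("16-bit TIFF export round-trips losslessly and clamps negatives", {
  skip_if_not_installed("tiff")
  path <- tempfile(fileext = ".tif")
  set.seed(31)
  pages <- list(matrix(sample(0:65535, 64 * 32, TRUE), 64, 32),
                matrix(sample(0:65535, 64 * 32, TRUE), 64, 32))
  export_tiff16(pages, path)
  back <- read_tiff16(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]], pages[[1]])
  expect_equal(back[[2]], pages[[2]])
  # negative unmixed values clamp at zero with a count
  neg <- matrix(c(-5, -1, 3, 10), 2, 2)
  expect_warning(info <- export_tiff16(neg, path), "clamped")
  expect_equal(info$n_negative_clamped, 2L)
  expect_equal(read_tiff16(path)[[1]], matrix(c(0, 0, 3, 10), 2, 2))
  # saturation above the 16-bit ceiling
  expect_warning(export_tiff16(matrix(7e4, 1, 1), path), "saturated")
})
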