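# mux2p

Temporal demultiplexing and fluorescence-lifetime analysis for
multiplexed two-photon microscopy.

## The problem

Large field-of-view two-photon microscopes trade field size against frame
rate: one laser focus has to raster the whole field. A way out is
*temporal multiplexing*: split a standard 80 MHz pulsed laser into four
copies delayed by 0, 3.125, 6.25 and 9.375 ns, excite four focal points
(two lateral positions × two depths), and let a single fast digitizer
(3.2 GS/s — 40 bins of 0.3125 ns per 12.5 ns pulse period) sort the
fluorescence by arrival time: four time gates after each pulse yield four
independent imaging channels at full speed. Because the same digitizer
resolves the fluorescence *decay* inside a pulse period, the identical
hardware also performs fluorescence lifetime imaging (FLIM).

`mux2p` implements this acquisition and analysis chain in software, for
people who build or study such systems:

- **Synthetic scope** — a digital twin of the front end:
  Poisson photon statistics, single-photon pulse shapes with the analog
  chain's ringing, two free-running 8 kHz resonant scanners, laser clock
  and sync streams, circulant inter-channel leakage
  (`simulate_pmt_stream()`, `make_phantom()`, `make_photon_kernel()`).
- **Pulse gating** — the FPGA's computation: 48-sample (15 ns) records per
  pulse with odd/even loop parity, four inclusive integration gates,
  16-bit saturation, 1/2/4-pulse accumulation (80 → 20 MHz per channel),
  single-photon event detection and statistics.
- **Crosstalk correction** — fluorescence tails leak into the gates
  sampled 3.125 k ns later with coefficients (a, b, c); the circulant
  model `J = WI`, `W = circ(1, a, b, c)`, is estimated from time-resolved
  single-beam calibration and inverted pulse-by-pulse (`unmix()`), before
  image reconstruction — the two scanners never synchronize, so
  image-level correction is impossible.
- **Reconstruction** — line assembly from each channel's own H-sync
  stream, bidirectional phase estimation, desinusoiding of the resonant
  sweep (`x = cos(pi s)`), lossless 16-bit multi-page TIFF export.
- **FLIM** — per-pixel estimation of `y_k = A (u ⊛ e^{-t/τ})_k + B` with
  the IRF `u` periodically extended over three periods: least squares,
  Poisson maximum likelihood, phasor analysis
  (`τ = tan φ / ω`), and a four-gate rapid-lifetime method whose gate
  positions a genetic algorithm (population 100, 100 generations,
  20 elites, ±1-bin mutations) optimizes against full 40-bin fits.
- **Traces** — neuropil background subtraction and the rolling
  8th-percentile / 30 s-Gaussian baseline that zeroes quiescent activity.

## Worked example

Simulate a bead phantom through the four-path scope, demultiplex, remove
crosstalk, reconstruct, and fit a lifetime:

```r
library(mux2p)

mux_pulse_delays(80e6, 4)
#> <mux_scheme> 80 MHz x 4 paths: spacing 3.125 ns, effective 320 MHz

cfg <- scope_config(resonant_freq = 312500, lines_per_frame = 24L,
                    pixels_per_line = 24L, noise_sd = 0.01,
                    scanner_phases = c(0.3, 1.7))
ph  <- make_phantom("beads", c(24L, 24L), n_objects = 8, seed = 5,
                    brightness = 25, taus = c(0.3, 0.5))
mix <- mixing_matrix(0.1, 0.05, 0.02)
mix
#> <mixing_model> circ(1, 0.1, 0.05, 0.02), condition 1.26

st  <- simulate_pmt_stream(ph, cfg, mixing = mix, seed = 21)
cnt <- unmix(integrate_gates(slice_pulse_records(st), default_gate_set()),
             mix)
geom <- geometry_from_config(
  cfg, first_line_forward = first_line_direction(st, 1, 1))
img <- desinusoid(assemble_frame(cnt, st$hsync1, st$vsync, geom,
                                 channel = 1))
cor(as.vector(img$pixels), as.vector(ph$brightness_maps[[1]]))
#> [1] 0.977
```

The reconstructed channel-1 image correlates at 0.98 with the ground
truth brightness map; channels 2–4 behave the same against their own
scanner's H-sync. Lifetime fitting on a noisy 40-bin decay:

```r
u <- ringing_irf()                       # 40-bin IRF with ringing
set.seed(1)
y <- rpois(40, convolve_model(u, 500, 2, 2.0))   # true tau = 2.0 ns
fit_lifetime_ls(y, u)
#> <lifetime_fit:ls> tau 1.982 ns, A 499.2, B 3.458, corr 0.9973
phasor_lifetime(y, u)
#> <phasor_point> g 0.5479 s 0.4680, phi 0.7069 rad, tau 1.699 ns
```

The least-squares fit recovers τ within 1%; the phasor lifetime carries
the small systematic offset of its min–max normalization but ranks
pixels identically to the fit.

A thin command-line interface wraps the same functions
(`Rscript inst/cli/mux2p.R plan`, `simulate`, `demux`, `calib-leakage`,
`reconstruct`, `flim-fit`, `ga-gates`, `noise-study`, `convert`); see
`Rscript inst/cli/mux2p.R --help`.

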