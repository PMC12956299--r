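---
title: "Temporal demultiplexing and lifetime estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal demultiplexing and lifetime estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mux2p)
```

# The measurement problem

A standard 80 MHz two-photon laser emits one pulse every 12.5 ns. If that
beam is split into four copies delayed by 0, 3.125, 6.25 and 9.375 ns, the
four copies can excite four different focal points (two lateral positions
at two depths each), and a single detector can tell the four fluorescence
signals apart by arrival time: fluorescence excited by path $k$ arrives
$k \times 3.125$ ns later than path 0's. A fast digitizer (3.2 GS/s, i.e.
40 samples of 0.3125 ns per pulse period) integrates four time gates after
each laser pulse and streams four 16-bit channel values per pulse — a
temporal demultiplexer in hardware. Because the digitizer resolves the
decay of fluorescence within a pulse period, the same hardware also
performs fluorescence lifetime imaging (FLIM).

`mux2p` re-expresses this acquisition and analysis chain in software, with
a synthetic signal generator standing in for the instrument. Everything
downstream of the generator — gating, crosstalk correction, image
reconstruction, lifetime estimation — is exactly the computation a real
acquisition would need.

# The synthetic scope

`simulate_pmt_stream()` renders a full-rate digitizer record from a ground
truth `phantom()` (per-path brightness maps in photons/pulse, a lifetime
map, object labels):

* **Laser clock.** Events every `sample_rate / rep_rate` samples (40 at
  defaults).
* **Scanners.** Two resonant scanners with position
  $x(t) = \cos(2\pi f_r t + \varphi_s)$, one line per half period, an
  H-sync event at every sweep boundary. The two scanners free-run, so
  their phases are independent — the property that forces crosstalk
  correction to act per pulse rather than per image. Only the central
  `fill_fraction` of the spatial sweep is imaged. The cosine kinematics is
  the standard resonant-scanner model; the functional form is assumed, not
  measured.
* **Photons.** For each pulse and path, a Poisson draw with mean equal to
  the brightness at the pixel the path's scanner currently addresses;
  each photon is delayed by the trigger delay, the path delay, and an
  exponential lifetime draw, then quantized to the 0.3125 ns grid.
  Sub-sample jitter is deliberately absent so that gate-level oracles are
  exact.
* **Pulse shape.** Each photon contributes a `make_photon_kernel()`
  waveform: a negative-going lobe of configurable FWHM (default 1.875 ns)
  followed by an exponentially damped oscillation — the ringing of the
  analog detection chain. Photons superpose linearly (no PMT saturation);
  Gaussian baseline noise is added per sample. The ringing amplitude and
  frequency are fixture parameters, not calibrated values: the real
  ringing is known only graphically.
* **Leakage.** When a `mixing_matrix()` is supplied, each photon also
  deposits fractions $a, b, c$ of its amplitude 10, 20 and 30 bins later,
  cyclically within the 12.5 ns period. The cyclic (steady-state) wrap
  makes the per-pulse gated channels obey $J = WI$ exactly; physically it
  assumes consecutive pulses address essentially the same pixel, which
  holds at realistic pixel dwell times of several pulses. By default the
  fluorescence decay tail is wrapped the same way (`periodic = TRUE`).

What the generator does **not** emulate: optical point-spread functions,
tunable-lens dynamics, laser intensity noise, PMT afterpulsing and
saturation, motion. Tests passing on this generator therefore validate
the *computational* chain — they say nothing about optical aberrations or
motion artefacts in real data.

Test geometries use a faster resonant frequency (312.5 kHz) than the
8 kHz hardware so that a frame occupies tens of microseconds of simulated
stream rather than milliseconds; all per-pulse arithmetic is unchanged,
since the pulse grid, not the line rate, carries the physics.

# Gating and accumulation

`slice_pulse_records()` cuts one 48-sample (15 ns) record per laser pulse.
Records overlap by 8 samples: fluorescence of the last path can arrive up
to ~14.4 ns after the trigger, beyond the 12.5 ns period, so each record
keeps 2.5 ns of headroom (mirrored in hardware by duplicated odd/even
processing loops — the parity tag on each record). `integrate_gates()`
sums polarity-corrected, baseline-offset samples over four user windows
(inclusive endpoints, 0-based time points) and saturates at the 16-bit
ceiling rather than wrapping. The stored sign convention of the real
hardware is unspecified; we negate the (negative-going) pulses so counts
are non-negative, with the baseline exposed as a parameter.
`default_gate_set()` opens the first gate 4 samples before the nominal
arrival because the photon lobe rises ahead of its trough; at defaults
the four 10-sample gates tile the full 40-bin period.
`accumulate_pulses()` sums 1, 2 or 4 consecutive pulses (80 → 20 MHz per
channel at 4).

# Crosstalk model

Fluorescence decays with nanosecond lifetimes, so each channel's tail
spills into the gates sampled 3.125, 6.25 and 9.375 ns later with
coefficients $a \ge b \ge c$. With channels enumerated cyclically this is
the circulant model

$$J = W I, \qquad W = \mathrm{circ}(1, a, b, c) =
\begin{pmatrix} 1 & a & b & c\\ c & 1 & a & b\\ b & c & 1 & a\\
a & b & c & 1\end{pmatrix}.$$

One convention needs care: in this layout row $j$ assigns coefficient $a$
to the channel one position *further along* the vector, so the matrix as
written applies to channels enumerated latest-gate-first. Package count
vectors are in acquisition-time order (earliest gate first), so
`unmix()` applies $W^\top{}^{-1}$ — equivalently, each channel receives
$a, b, c$ times the channels gated one, two, three steps *earlier*,
which is the physical direction of a decay tail. The convention is
validated end-to-end by the ghost-image test: a specimen present only on
path 1, reconstructed on a path-2 channel against scanner 1's H-sync,
leaves a coherent ghost that drops below 1% of its power after unmixing.

Coefficients are estimated by `estimate_leakage()` from a single-beam
time-resolved calibration: the 40-bin mean profile's sums over the main
gate shifted cyclically by +10, +20, +30 bins, divided by the main-gate
sum. Ratios of *gate sums* (not peak values) are used because gate sums
are what the hardware integrates. Unmixed counts stay in floating point;
re-quantizing to 16 bits before reconstruction would only add bias.

# Image reconstruction

`assemble_frame()` forms one line from the pulses between consecutive
H-syncs of the channel's own scanner (path-1 channels use H-sync 1,
path-2 channels H-sync 2), starting at the first H-sync after the frame's
V-sync. H-sync is taken to mark the sweep start (the hardware leaves the
sync phase undefined; it is configurable). Backward sweeps are stored
flipped with their within-sweep phases mirrored, so that all lines share
the forward convention. `estimate_bidirectional_offset()` cross-correlates
mean forward against mean backward profiles with parabolic subpixel
refinement. `desinusoid()` resamples each line from uniform-in-time
pulses to uniform-in-space pixels through $x = \cos(\pi s)$ cropped to
the central fill fraction, by linear interpolation — chosen over pixel
binning because it is order-preserving, integral-conserving to
interpolation accuracy, and trivially testable. Export is lossless
16-bit multi-page TIFF; negative unmixed values clamp at zero with a
count, overflow saturates with a warning.

# Lifetime estimation

Per pixel the 40-bin decay $y_k$ is modelled as the instrument response
$u$ (unit-sum normalized, so the amplitude lives in $A$) convolved with a
mono-exponential plus offset:

$$\hat y_k(A, B, \tau) = A\,(u \circledast e_\tau)_k + B,
\qquad e_\tau(t) = e^{-t/\tau},$$

where the exponential is sampled over three consecutive pulse periods and
folded — the periodic extension $[u\,u\,u]$ that avoids wrap-around bias
at the 12.5 ns boundary while truncating negligible mass beyond three
periods. `convolve_model()` is checked against a scalar triple-loop
oracle to $10^{-12}$.

* **Least squares** (`fit_lifetime_ls()`): for each candidate $\tau$ the
  amplitudes $(A, B) \ge 0$ are a closed-form linear solve, so the search
  is one-dimensional — a coarse log-spaced grid brackets the optimum,
  then a bounded search refines it. $\tau$ is searched in
  [0.3125, 12.5] ns by default; one bin width is the natural lower
  resolution limit and one period the upper. The residual is the sum of
  squares.
* **Poisson MLE** (`fit_lifetime_poisson()`): minimizes
  $\sum_k (\lambda_k - y_k \log \lambda_k)$ in
  $(\log A, \log B, \log\tau)$ (positivity by construction) with
  analytic gradients, initialized from the LS fit; $\lambda$ is floored
  at $10^{-10}$ against log-of-zero.
* **Phasor** (`phasor_lifetime()`): first-harmonic coordinates of the
  min-max-normalized trace, divided (as complex numbers) by the IRF's
  coordinates; $\tau = \tan\varphi/\omega$. Min-max normalization shifts
  the DC component, so phasor lifetimes carry a small systematic offset
  relative to fits — their *ranking* agrees with LS to Spearman
  $\ge 0.99$ on noiseless stacks, which is what the method is used for.
* **Four-gate** (`four_gate_lifetime()`): gate means of the
  (reference-shifted, baseline-subtracted) trace fitted against gate
  means of the model, amplitude linear per $\tau$, $\tau$ by a bounded
  1-D search with tolerance $10^{-4}$. A gate gene is eight ordered bins
  $b_1 \le b_2 < b_3 \le b_4 < b_5 \le b_6 < b_7 \le b_8$; gate values
  average the full inclusive range (not only the endpoints — the other
  reading of "the corresponding bins", available by constructing
  single-bin windows). The reference shift default is 19 bins.

`fit_lifetime_image()` vectorizes the LS path over all pixels on a shared
$\tau$ grid (closed-form amplitudes per grid point, parabolic refinement
of the grid minimum); pixels below a brightness percentile (default
50th) are skipped, as dim pixels yield unidentifiable fits.

# Genetic gate optimization

`ga_optimize_gates()` evolves gate genes toward maximal Pearson
correlation between four-gate lifetimes and the full 40-bin LS lifetimes
over 120 randomly chosen bright pixels: population 100, 100 generations,
20 elites kept unchanged, 80 offspring formed by shifting one bin of a
random elite by ±1, duplicates removed. The fitness pixel set is drawn
once per run from the seed and held fixed across generations — resampling
would make fitness values incomparable between generations. Elitism
makes the best fitness non-decreasing, which the tests assert. Inside the
GA the per-pixel $\tau$ search runs on a shared fine grid with parabolic
refinement instead of per-pixel `optimize()` calls; gene fitness values
are cached, so converged populations cost almost nothing to re-score.

# The noise study

`lifetime_noise_study()` asks how many images an accurate lifetime needs:
draw a pool of 200 noisy images per noise model (Gaussian with
shot-matched variance, or Poisson), estimate lifetimes from the first
$n$ images for each $n$, and measure the mean absolute error against the
200-image estimate of the same pool — so the $n = 200$ point is zero by
definition and nesting makes the error non-increasing in $n$.

Two modelling choices matter here:

* **Brightness range.** The error of the top-10%-brightest pixels is only
  meaningful if brightness varies; the study is normally run with a
  brightness map spanning about a decade (as real specimens do).
* **Read noise.** The generator adds Gaussian measurement noise
  (default sd 3 counts/bin/image) on top of photon statistics. The
  detection chain is an analog amplifier plus digitizer, which has a
  noise floor irrespective of photon counts. This term is what makes
  Poisson-likelihood estimation no better than least squares in the
  study: with pure shot noise at low counts the MLE genuinely wins,
  but a misspecified Poisson model loses its edge once a comparable
  additive component is present — the regime this instrument class
  operates in.

Problem sizes in the tests (12×12 to 30×20 pixel maps, pools of 200
images, 24×24-pixel simulated frames) are the package's chosen desk-scale
defaults; every routine accepts larger inputs unchanged.

# Degenerate inputs and numerical conventions

Constant traces: LS reports $A = 0$ and `converged = FALSE`; the phasor
flags `undefined`; the four-gate search pins at a bound and sets a
`boundary` flag. Featureless images give a zero bidirectional shift with
a `low_confidence` flag. Ill-conditioned mixing matrices (e.g.
$a = b = c = 1$, which is singular) are refused at construction. Gate
sums saturate rather than wrap. All stochastic routines take explicit
seeds and restore the caller's RNG state; identical seeds give
bit-identical outputs.

Times are in ns, rates in Hz, lengths in m or µm as documented — there
are no implicit unit conversions. The free-space delay length helper
defaults to $c = 3.0\times10^8$ m/s, the rounding under which a 6.25 ns
loop is the conventionally quoted 1.88 m; exact $c$ can be passed.
The power-split model is the lossless ideal: transmission losses of the
in-loop optics are not modelled, as no loss figures are available.

# Known limitations

Mono-exponential decays only (no multi-exponential or FRET-efficiency
models); linear PMT response; no TCSPC or TDMS import (the native
container is a versioned RDS payload plus CSV/JSON interchange, as no
HDF5 or TDMS binding is available to the package); crosstalk is the
linear circulant model — saturation-induced or spectral mixing is out of
scope. Registration, ROI detection and clustering of the downstream
calcium-imaging workflow are the province of dedicated external tools
and are deliberately not reimplemented; `mux2p` ends at
background-subtracted, baseline-zeroed ROI traces.
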