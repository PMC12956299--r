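# Shared fixtures: a desk-scale scope configuration (fast resonant mirror
# so frames stay small), a narrow ring-free photon kernel that keeps gate
# oracles exact, and scalar reference implementations used as independent
# oracles for the vectorized code paths.

test_config <- function(lines = 24L, pixels = 24L, noise_sd = 0.01,
                        phases = c(0.3, 1.7)) {
  scope_config(resonant_freq = 312500, lines_per_frame = lines,
               pixels_per_line = pixels, noise_sd = noise_sd,
               scanner_phases = phases)
}

test_kernel <- function() make_photon_kernel(fwhm_ns = 0.9, ring_amp = 0)

# Scalar per-sample gate integration (the FPGA's definition, one sample at
# a time) used as the oracle for integrate_gates().
oracle_gate_sums <- function(records, gates, baseline = 0,
                             polarity = "negative", clip = TRUE) {
  out <- matrix(0, nrow(records), 4)
  for (p in seq_len(nrow(records))) {
    for (g in 1:4) {
      s <- 0
      for (j in gates$gates[g, 1]:gates$gates[g, 2]) {
        v <- records[p, j + 1]
        s <- s + if (polarity == "negative") baseline - v else v - baseline
      }
      out[p, g] <- if (clip) min(max(s, 0), 65535) else s
    }
  }
  out
}

# Scalar triple-period convolution: the defining oracle for the
# IRF-convolved mono-exponential model.
oracle_convolve_model <- function(u, A, B, tau, dt = 0.3125) {
  nb <- length(u)
  out <- numeric(nb)
  for (k in 0:(nb - 1)) {
    s <- 0
    for (m in 0:(nb - 1)) {
      for (p in 0:2) {
        lag <- ((k - m) %% nb) + p * nb
        s <- s + u[m + 1] * exp(-lag * dt / tau)
      }
    }
    out[k + 1] <- A * s + B * sum(u)
  }
  out
}

decay_basis_ <- function(...) mux2p:::decay_basis(...)
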