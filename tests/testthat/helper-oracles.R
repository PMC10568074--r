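# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they check.

# Reference Bloch integrator: classical RK4 on
#   dM/dt = M x omega(t) + relaxation,
# with the RF waveform held constant within each pulse sample and `substeps`
# RK4 steps per sample. Same physics as bloch_evolve() but a different
# discretisation, so agreement is evidence both are right.
rk4_bloch <- function(pulse, t1_ms, t2_ms, m_init = c(0, 0, 1),
                      substeps = 8L) {
  t1 <- t1_ms / 1000; t2 <- t2_ms / 1000
  dt <- pulse$duration_ms / 1000 / pulse$n_samples / substeps
  deriv <- function(m, wx, wz) {
    c(m[2] * wz - m[1] / t2,
      m[3] * wx - m[1] * wz - m[2] / t2,
      -m[2] * wx - (m[3] - 1) / t1)
  }
  m <- m_init
  for (i in seq_len(pulse$n_samples)) {
    wx <- 2 * pi * pulse$amplitude_hz[i]
    wz <- -2 * pi * pulse$freq_offset_hz[i]
    for (s in seq_len(substeps)) {
      k1 <- deriv(m, wx, wz)
      k2 <- deriv(m + dt / 2 * k1, wx, wz)
      k3 <- deriv(m + dt / 2 * k2, wx, wz)
      k4 <- deriv(m + dt * k3, wx, wz)
      m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  m
}

# Exhaustive grid-search oracle for the optimal inversion time: evaluates
# the suppression objective on a 0.01 ms TI grid with no refinement.
exhaustive_ti <- function(spec, objective = "lsq", step = 0.01) {
  tis <- seq(step, spec$tr_ms - step, by = step)
  obj <- vapply(tis, function(ti) {
    r <- 1 - spec$q_long * exp(-spec$tr_ms / spec$t1_grid) -
      (1 - spec$q_long) * exp(-ti / spec$t1_grid)
    if (objective == "lsq") mean(r^2) else max(abs(r))
  }, numeric(1))
  tis[which.min(obj)]
}

# Closed-form inversion time that nulls a single T1 at repetition time TR
# (perfect inversion): TI = -T1 * log((1 + exp(-TR/T1)) / 2).
null_ti <- function(t1_ms, tr_ms) -t1_ms * log((1 + exp(-tr_ms / t1_ms)) / 2)

# small phantom spec used where full resolution is unnecessary
tiny_spec <- function(...) {
  phantom_spec(shape = c(24, 24, 7), n_lesions = 2L,
               lesion_radius_vox = c(1, 1.8), n_rois = 2L,
               roi_radius_vox = 2, ...)
}
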