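# Closed-form steady-state signal model for short-TR adiabatic
# inversion-recovery imaging, plus an explicit cycle-recursion oracle.

# internal: pre-TE longitudinal factor of the steady state.
# Derivation: each cycle the 90 deg excitation zeroes Mz; it recovers for
# (TR - TI), is scaled by q at the inversion, recovers for TI, and is read
# out. At steady state the recursion is a fixed point whose readout is
# 1 - q e^{-TR/T1} - (1 - q) e^{-TI/T1} per unit m0.
stair_longitudinal <- function(t1_ms, tr_ms, ti_ms, q) {
  1 - q * exp(-tr_ms / t1_ms) - (1 - q) * exp(-ti_ms / t1_ms)
}

#' Steady-state signal of the STAIR sequence
#'
#' Signed steady-state signal of one water compartment under a short-TR
#' adiabatic inversion-recovery acquisition with 90 degree excitation:
#' \deqn{S = M_0 \left(1 - Q e^{-TR/T_1} - (1-Q) e^{-TI/T_1}\right)
#'   e^{-TE/T_2^*}.}
#' The value is signed (no magnitude is taken) so that null crossings of the
#' longitudinal state are observable; magnitude enters only through the
#' phantom's noise stage.
#'
#' @param pool A [relaxation_pool()].
#' @param seq A [seq_params()]; must carry an inversion time and a 90 degree
#'   flip angle (the model assumes the excitation zeroes the longitudinal
#'   magnetization every cycle and refuses other flip angles rather than
#'   silently approximating).
#'
#' @return Signal in the units of `pool$m0`; may be negative.
#' @seealso [steady_state_oracle()] for an independent cycle-by-cycle check,
#'   [pd_signal()], [mw_signal_scale()].
#' @export
#' @examples
#' mw <- relaxation_pool(1, t1_ms = 220, t2s_ms = 10, q = -0.75)
#' stair_signal(mw, seq_params(250, 117, 5.5))
stair_signal <- function(pool, seq) {
  stopifnot(inherits(pool, "relaxation_pool"), inherits(seq, "seq_params"))
  if (is.null(seq$ti_ms))
    abort("STAIR signal requires an inversion time (`ti_ms`).",
          class = "stairmwi_invalid_protocol")
  if (seq$flip_deg != 90)
    abort("The steady-state model is only valid for a 90 degree excitation.",
          class = "stairmwi_invalid_protocol")
  pool$m0 * stair_longitudinal(pool$t1_ms, seq$tr_ms, seq$ti_ms, pool$q) *
    exp(-seq$te_ms / pool$t2s_ms)
}

#' Proton-density-weighted signal
#'
#' Signal of the proton-density reference acquisition,
#' \eqn{S = M_0 e^{-TE/T_2^*}}. The model deliberately ignores TR and flip
#' angle: with a small excitation angle and long effective recovery the
#' acquisition is treated as purely proton-density weighted.
#'
#' @inheritParams stair_signal
#' @return Signal in the units of `pool$m0`.
#' @export
#' @examples
#' pd_signal(relaxation_pool(1, 1000, 60), pd_protocol())
pd_signal <- function(pool, seq) {
  stopifnot(inherits(pool, "relaxation_pool"), inherits(seq, "seq_params"))
  pool$m0 * exp(-seq$te_ms / pool$t2s_ms)
}

#' Myelin-water signal per unit magnetization
#'
#' The steady-state STAIR signal of the myelin-water pool per unit
#' equilibrium magnetization, i.e. [stair_signal()] evaluated with the fixed
#' myelin-water constants (T1 = 220 ms, T2* = 10 ms, Q = -0.75 by default)
#' and `m0 = 1`. This is the denominator scale that the aMWF estimator
#' divides out.
#'
#' @param constants A [quant_constants()].
#' @param seq A [seq_params()] with TR, TI and TE.
#' @return Dimensionless scale.
#' @export
#' @examples
#' mw_signal_scale(quant_constants(), stair_protocol())
mw_signal_scale <- function(constants, seq) {
  stopifnot(inherits(constants, "quant_constants"))
  pool <- relaxation_pool(1, constants$t1_mw_ms, constants$t2s_mw_ms,
                          constants$q_mw)
  stair_signal(pool, seq)
}

#' Cycle-recursion oracle for the steady-state signal
#'
#' Simulates the acquisition cycle explicitly instead of using the
#' closed-form fixed point: starting from equilibrium, each cycle the
#' 90 degree excitation sets the longitudinal magnetization to zero, it
#' recovers freely for (TR - TI), the adiabatic pulse scales it by Q, it
#' recovers for TI, and the readout applies \eqn{e^{-TE/T_2^*}}. After
#' enough cycles the readout converges to [stair_signal()]; the two routes
#' are kept independent so each can verify the other.
#'
#' @inheritParams stair_signal
#' @param n_cycles Number of cycles to iterate (>= 1).
#' @return Readout signal of the last cycle.
#' @export
steady_state_oracle <- function(pool, seq, n_cycles = 200L) {
  stopifnot(inherits(pool, "relaxation_pool"), inherits(seq, "seq_params"))
  if (is.null(seq$ti_ms))
    abort("STAIR cycle requires an inversion time (`ti_ms`).",
          class = "stairmwi_invalid_protocol")
  if (seq$flip_deg != 90)
    abort("The cycle oracle assumes a 90 degree excitation.",
          class = "stairmwi_invalid_protocol")
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  relax <- function(mz, t_ms) pool$m0 + (mz - pool$m0) * exp(-t_ms / pool$t1_ms)
  mz <- pool$m0
  readout <- NA_real_
  for (i in seq_len(n_cycles)) {
    mz <- relax(0, seq$tr_ms - seq$ti_ms)  # excitation zeroed Mz, recover
    mz <- pool$q * mz                      # adiabatic inversion
    mz <- relax(mz, seq$ti_ms)             # recover until excitation
    readout <- mz * exp(-seq$te_ms / pool$t2s_ms)
  }
  readout
}
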