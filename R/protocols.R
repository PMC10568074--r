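#' Sequence parameters for one acquisition
#'
#' Bundles the timing and averaging parameters of a single EPI acquisition.
#' All times are in milliseconds; configurations on a seconds scale are
#' rejected (a repetition time above 10,000 ms almost certainly means the
#' value was given in microseconds or mis-scaled).
#'
#' @param tr_ms Repetition time (ms), > 0.
#' @param ti_ms Inversion time (ms), in (0, `tr_ms`); `NULL` for sequences
#'   without an inversion preparation (e.g. the proton-density reference).
#' @param te_ms Echo time (ms), >= 0.
#' @param flip_deg Excitation flip angle (degrees), in (0, 90].
#' @param nex Number of excitations averaged, integer >= 1.
#' @param label Free-text label carried into volume metadata.
#'
#' @return An object of class `seq_params`.
#' @seealso [stair_protocol()], [pd_protocol()] for the default protocols.
#' @export
#' @examples
#' seq_params(tr_ms = 250, ti_ms = 117, te_ms = 5.5)
seq_params <- function(tr_ms, ti_ms = NULL, te_ms = 0, flip_deg = 90,
                       nex = 1L, label = "") {
  if (!is.numeric(tr_ms) || length(tr_ms) != 1 || tr_ms <= 0)
    abort("`tr_ms` must be a single positive number (ms).")
  if (tr_ms > 10000)
    warn("`tr_ms` exceeds 10,000 ms; times must be in milliseconds.")
  if (!is.numeric(te_ms) || length(te_ms) != 1 || te_ms < 0)
    abort("`te_ms` must be a single non-negative number (ms).")
  if (!is.numeric(flip_deg) || flip_deg <= 0 || flip_deg > 90)
    abort("`flip_deg` must be in (0, 90].")
  if (!is.numeric(nex) || length(nex) != 1 || nex < 1 || nex != round(nex))
    abort("`nex` must be a positive integer.")
  if (!is.null(ti_ms)) {
    if (!is.numeric(ti_ms) || length(ti_ms) != 1 || ti_ms <= 0 || ti_ms >= tr_ms)
      abort("`ti_ms` must satisfy 0 < TI < TR.")
  }
  structure(
    list(tr_ms = tr_ms, ti_ms = ti_ms, te_ms = te_ms,
         flip_deg = flip_deg, nex = as.integer(nex), label = label),
    class = "seq_params"
  )
}

#' @export
print.seq_params <- function(x, ...) {
  ti <- if (is.null(x$ti_ms)) "-" else format(x$ti_ms)
  cat(sprintf("<seq_params> %s  TR/TI/TE = %s/%s/%s ms, FA = %s deg, NEX = %d\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              format(x$tr_ms), ti, format(x$te_ms), format(x$flip_deg), x$nex))
  invisible(x)
}

#' Default STAIR-EPI and PD-EPI protocols
#'
#' The in-vivo whole-brain protocols at 3 T: STAIR-EPI with
#' TR/TI/TE = 250/117/5.5 ms, 90 degree excitation and NEX = 30, and the
#' proton-density-weighted reference PD-EPI with TR/TE = 250/5.5 ms,
#' 5 degree excitation and NEX = 10.
#'
#' @return A `seq_params` object.
#' @export
stair_protocol <- function() {
  seq_params(tr_ms = 250, ti_ms = 117, te_ms = 5.5, flip_deg = 90,
             nex = 30L, label = "STAIR-EPI")
}

#' @rdname stair_protocol
#' @export
pd_protocol <- function() {
  seq_params(tr_ms = 250, ti_ms = NULL, te_ms = 5.5, flip_deg = 5,
             nex = 10L, label = "PD-EPI")
}

#' One relaxing water compartment
#'
#' @param m0 Equilibrium longitudinal magnetization (arbitrary units, >= 0).
#' @param t1_ms Longitudinal relaxation time (ms), > 0.
#' @param t2s_ms Effective transverse relaxation time T2* (ms), > 0.
#' @param q Inversion efficiency applied by the adiabatic pulse: -1 is full
#'   inversion, 1 leaves the longitudinal magnetization untouched.
#'
#' @return An object of class `relaxation_pool`.
#' @export
#' @examples
#' relaxation_pool(m0 = 1, t1_ms = 220, t2s_ms = 10, q = -0.75)
relaxation_pool <- function(m0, t1_ms, t2s_ms, q = -1) {
  if (!is.numeric(m0) || length(m0) != 1 || m0 < 0)
    abort("`m0` must be a single non-negative number.")
  if (!is.numeric(t1_ms) || length(t1_ms) != 1 || t1_ms <= 0)
    abort("`t1_ms` must be a single positive number (ms).")
  if (!is.numeric(t2s_ms) || length(t2s_ms) != 1 || t2s_ms <= 0)
    abort("`t2s_ms` must be a single positive number (ms).")
  if (!is.numeric(q) || length(q) != 1 || q < -1 || q > 1)
    abort("`q` must lie in [-1, 1].")
  structure(list(m0 = m0, t1_ms = t1_ms, t2s_ms = t2s_ms, q = q),
            class = "relaxation_pool")
}

#' Fixed constants assumed by the aMWF estimator
#'
#' The quantification step treats myelin water as a single pool with known
#' relaxation times and inversion efficiency, and total water as a single
#' pool with a known T2*. Defaults are the literature values used
#' throughout: T1,MW = 220 ms, T2*,MW = 10 ms, T2*,total = 60 ms,
#' Q_MW = -0.75 for an 8.64 ms adiabatic full-passage pulse, Q = -1 for
#' long-T1 water, and a suppression band of T1 in \[600, 2000\] ms.
#'
#' @param t1_mw_ms,t2s_mw_ms Myelin-water T1 and T2* (ms).
#' @param t2s_total_ms Total-water T2* (ms).
#' @param q_mw Inversion efficiency of myelin water (short T2* makes the
#'   adiabatic inversion incomplete).
#' @param q_long Inversion efficiency of long-T1/long-T2* water.
#' @param t1_suppress_lo_ms,t1_suppress_hi_ms T1 band (ms) over which the
#'   inversion time is optimised to null long-T1 water.
#'
#' @return An object of class `quant_constants`.
#' @export
quant_constants <- function(t1_mw_ms = 220, t2s_mw_ms = 10,
                            t2s_total_ms = 60, q_mw = -0.75, q_long = -1,
                            t1_suppress_lo_ms = 600,
                            t1_suppress_hi_ms = 2000) {
  times <- c(t1_mw_ms, t2s_mw_ms, t2s_total_ms,
             t1_suppress_lo_ms, t1_suppress_hi_ms)
  if (any(!is.finite(times)) || any(times <= 0))
    abort("All relaxation times and band edges must be positive.")
  if (t1_suppress_lo_ms >= t1_suppress_hi_ms)
    abort("`t1_suppress_lo_ms` must be below `t1_suppress_hi_ms`.")
  for (q in c(q_mw, q_long))
    if (!is.numeric(q) || q < -1 || q > 1) abort("Q values must lie in [-1, 1].")
  structure(
    list(t1_mw_ms = t1_mw_ms, t2s_mw_ms = t2s_mw_ms,
         t2s_total_ms = t2s_total_ms, q_mw = q_mw, q_long = q_long,
         t1_suppress_lo_ms = t1_suppress_lo_ms,
         t1_suppress_hi_ms = t1_suppress_hi_ms),
    class = "quant_constants"
  )
}
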