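# Inversion-time design: pick the TI that best nulls fully inverted
# long-T1 water across a whole T1 band at a given short TR.

#' Long-T1 suppression specification
#'
#' Describes the band of long-T1 water to suppress at a given repetition
#' time. The suppression band defaults to T1 in \[600, 2000\] ms, covering
#' intra/extracellular water and CSF-like species; the inversion is assumed
#' complete (Q = -1) for these pools. The residual is evaluated on a uniform
#' T1 grid (141 points, i.e. 10 ms spacing for the default band).
#'
#' @param tr_ms Repetition time (ms). A warning is issued outside
#'   \[180, 300\] ms, the range with reasonable contrast-to-noise efficiency
#'   for myelin-water imaging.
#' @param t1_lo_ms,t1_hi_ms Band edges (ms), `t1_lo_ms < t1_hi_ms`.
#' @param q_long Inversion efficiency assumed for the band.
#' @param n_grid Number of uniform T1 grid points (>= 2).
#'
#' @return An object of class `suppression_spec`.
#' @export
#' @examples
#' suppression_spec(tr_ms = 250)
suppression_spec <- function(tr_ms, t1_lo_ms = 600, t1_hi_ms = 2000,
                             q_long = -1, n_grid = 141L) {
  if (tr_ms <= 0) abort("`tr_ms` must be positive.")
  if (tr_ms < 50 || tr_ms > 1000)
    warn("`tr_ms` outside the sane 50-1000 ms band for this application.")
  else if (tr_ms < 180 || tr_ms > 300)
    warn("TR outside [180, 300] ms: contrast-to-noise efficiency degrades.")
  if (t1_lo_ms >= t1_hi_ms && !(t1_lo_ms == t1_hi_ms && n_grid >= 1))
    abort("`t1_lo_ms` must not exceed `t1_hi_ms`.")
  if (n_grid < 2 && t1_lo_ms != t1_hi_ms) abort("`n_grid` must be >= 2.")
  structure(
    list(tr_ms = tr_ms, t1_lo_ms = t1_lo_ms, t1_hi_ms = t1_hi_ms,
         q_long = q_long, n_grid = as.integer(max(n_grid, 1)),
         t1_grid = if (t1_lo_ms == t1_hi_ms) t1_lo_ms
                   else seq(t1_lo_ms, t1_hi_ms, length.out = n_grid)),
    class = "suppression_spec"
  )
}

#' Residual long-T1 signal across the suppression band
#'
#' Pre-readout steady-state signal per unit magnetization,
#' \eqn{1 - Q e^{-TR/T_1} - (1-Q) e^{-TI/T_1}}, evaluated on the spec's
#' uniform T1 grid. With Q = -1 this is \eqn{1 + e^{-TR/T_1} - 2e^{-TI/T_1}},
#' the quantity the inversion time is chosen to null.
#'
#' @param spec A [suppression_spec()].
#' @param ti_ms Inversion time (ms), in (0, TR).
#' @return A tibble with columns `t1_ms` and `signal` (fraction of m0).
#' @export
#' @examples
#' residual_signal_profile(suppression_spec(250), ti_ms = 117)
residual_signal_profile <- function(spec, ti_ms) {
  stopifnot(inherits(spec, "suppression_spec"))
  if (ti_ms <= 0 || ti_ms >= spec$tr_ms)
    abort("`ti_ms` must satisfy 0 < TI < TR.")
  tibble(
    t1_ms = spec$t1_grid,
    signal = stair_longitudinal(spec$t1_grid, spec$tr_ms, ti_ms, spec$q_long)
  )
}

# internal: mean squared / max absolute residual over the grid
suppression_objective <- function(spec, ti_ms, objective = "lsq") {
  r <- stair_longitudinal(spec$t1_grid, spec$tr_ms, ti_ms, spec$q_long)
  switch(objective, lsq = mean(r^2), minimax = max(abs(r)),
         abort("`objective` must be 'lsq' or 'minimax'."))
}

#' Optimal inversion time for broadband long-T1 suppression
#'
#' Minimizes the residual long-T1 signal over the suppression band. The
#' default objective is the mean squared residual on the uniform T1 grid
#' (which lands on TI = 117 ms for TR = 250 ms and the 600-2000 ms band); a
#' minimax objective over the same grid is available as an alternative.
#' The minimum is located by a 1 ms grid scan over (0, TR) followed by
#' golden-section/parabolic refinement of the bracketing interval to 0.01 ms.
#'
#' @param spec A [suppression_spec()].
#' @param objective `"lsq"` (mean squared residual, default) or `"minimax"`
#'   (worst absolute residual over the band).
#' @return Optimal TI in ms (full precision; round for protocol cards).
#' @export
#' @examples
#' round(optimal_ti(suppression_spec(250)))  # 117
optimal_ti <- function(spec, objective = c("lsq", "minimax")) {
  stopifnot(inherits(spec, "suppression_spec"))
  objective <- match.arg(objective)
  if (length(spec$t1_grid) == 1) {
    # single-T1 band: the null has a closed form for q = -1
    if (spec$q_long == -1) {
      t1 <- spec$t1_grid
      return(-t1 * log((1 + exp(-spec$tr_ms / t1)) / 2))
    }
  }
  coarse <- seq(1, spec$tr_ms - 1, by = 1)
  vals <- vapply(coarse, function(ti) suppression_objective(spec, ti, objective),
                 numeric(1))
  i <- which.min(vals)
  lo <- coarse[max(i - 1L, 1L)]
  hi <- coarse[min(i + 1L, length(coarse))]
  optimize(function(ti) suppression_objective(spec, ti, objective),
           interval = c(lo, hi), tol = 1e-3)$minimum
}

#' Worst-case residual over the suppression band
#'
#' @inheritParams residual_signal_profile
#' @return Maximum absolute residual signal over the T1 grid, as a fraction
#'   of m0 (pre-readout).
#' @export
#' @examples
#' spec <- suppression_spec(250)
#' max_residual(spec, optimal_ti(spec))  # ~ 0.013
max_residual <- function(spec, ti_ms) {
  max(abs(residual_signal_profile(spec, ti_ms)$signal))
}

#' Myelin-water signal across repetition times
#'
#' For each TR, finds the band-optimal TI and evaluates the steady-state
#' myelin-water signal per unit magnetization there (pre-readout, TE = 0).
#' Longer TRs allow more recovery and hence more myelin-water signal, at the
#' cost of scan time; this curve documents the trade-off qualitatively.
#'
#' @param tr_grid_ms Vector of repetition times (ms), all positive.
#' @param constants A [quant_constants()] supplying the myelin-water
#'   relaxation times, Q and the suppression band.
#' @return A tibble with columns `tr_ms`, `ti_ms`, `mw_signal`.
#' @export
mw_contrast_vs_tr <- function(tr_grid_ms, constants = quant_constants()) {
  if (any(tr_grid_ms <= 0)) abort("All TR values must be positive.")
  purrr::map_dfr(tr_grid_ms, function(tr) {
    spec <- suppression_spec(tr, constants$t1_suppress_lo_ms,
                             constants$t1_suppress_hi_ms, constants$q_long)
    ti <- optimal_ti(spec)
    tibble(
      tr_ms = tr, ti_ms = ti,
      mw_signal = stair_longitudinal(constants$t1_mw_ms, tr, ti, constants$q_mw)
    )
  })
}
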