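# stairmwi

Myelin water imaging with short-TR adiabatic inversion-recovery (STAIR) EPI.

Myelin water — the water trapped between myelin bilayers — has much shorter
T1 (~220 ms) and T2* (~10 ms) than intra/extracellular water, and its
fraction of total water (the myelin water fraction) drops where myelin is
lost, as in multiple-sclerosis lesions. The STAIR preparation suppresses the
long-T1 water pool across a whole band of T1 values by pairing a short
repetition time with an optimized inversion time, leaving a signal that is
essentially pure myelin water. Dividing that image by a proton-density
reference and removing the known signal scales yields a voxel-wise
*apparent* myelin water fraction (aMWF) map.

`stairmwi` implements the full quantitative chain for this method in R:

* **Signal model** — the steady-state inversion-recovery signal
  `S = M0 (1 − Q e^(−TR/T1) − (1−Q) e^(−TI/T1)) e^(−TE/T2*)` for a 90°
  excitation, the proton-density signal `S = M0 e^(−TE/T2*)`, and an
  independent cycle-recursion oracle (`stair_signal()`, `pd_signal()`,
  `steady_state_oracle()`).
* **Protocol design** — the inversion time that minimizes the residual
  long-T1 signal over T1 ∈ [600, 2000] ms at a given TR
  (`optimal_ti()`, `residual_signal_profile()`, `max_residual()`).
* **Pulse physics** — Bloch simulation with relaxation of the 8.64 ms
  hyperbolic-secant adiabatic inversion pulse, giving the inversion
  efficiency Q as a function of T2 and justifying Q_MW ≈ −0.75 for myelin
  water and Q ≈ −1 for long-T2 water (`hs_pulse()`, `bloch_evolve()`,
  `inversion_efficiency()`, `calibrate_peak_b1()`).
* **Quantification** — voxel-wise `aMWF = k · S_STAIR / S_PD` with
  `k = amwf_scale_factor()` ≈ 7.44 for the default protocols, plus masking
  and ROI statistics (`compute_amwf_map()`, `make_mask()`,
  `extract_roi_stats()`).
* **Digital phantom** — a labeled synthetic brain with two-compartment
  voxels, lesions, Rician noise and NEX averaging, and whole-cohort
  simulation with between-subject variability (`phantom_spec()`,
  `build_label_map()`, `simulate_acquisition()`, `simulate_cohort()`,
  `recover_group_means()`).
* **Group statistics** — Kolmogorov–Smirnov (Lilliefors) normality check,
  one-way ANOVA and Games–Howell post hoc with studentized-range adjusted
  p-values (`ks_normality()`, `one_way_anova()`, `games_howell()`,
  `summarize_cohort()` with `tidy()`/`glance()`/`autoplot()` methods).

Functions take and return tibbles where the data are tabular; image volumes
are 3-D arrays with voxel metadata, read and written as NIfTI-1. A thin
command-line wrapper lives in `exec/stairmwi`
(`optimize-ti | bloch-q | simulate-phantom | compute-amwf | roi-stats |
group-stats`).

## Worked example

Design the protocol, simulate a patient cohort, quantify it, and compare
groups:

```r
library(stairmwi)

# 1. optimal TI for long-T1 suppression at TR = 250 ms
spec <- suppression_spec(tr_ms = 250)          # T1 band 600-2000 ms
ti <- optimal_ti(spec)
round(ti)                                      # 117 (ms)
max_residual(spec, ti)                         # 0.0128 of M0 (worst case)

# 2. inversion efficiency of the calibrated adiabatic pulse
b1 <- calibrate_peak_b1()                      # 700 (Hz)
pulse <- hs_pulse(peak_b1_hz = b1)
inversion_efficiency(pulse, t1_ms = 1000, t2_ms = 2000)  # -0.986 (long T2)
inversion_efficiency(pulse, t1_ms = 220, t2_ms = 10)     # -0.836 (myelin water)

# 3. simulate a 7-control + 7-patient cohort and quantify it
cohort <- simulate_cohort(phantom_spec(seed = 1), seed = 1)
obs <- quantify_cohort(cohort)
report <- summarize_cohort(obs)
report
#> Groups:
#>   group  n    mean       sd conf_low conf_high
#>  lesion 63 0.03882 0.013182  0.03550   0.04214
#>    NAWM 56 0.08552 0.006618  0.08374   0.08729
#>     NWM 56 0.09534 0.010192  0.09261   0.09807
#>
#> One-way ANOVA: F(2, 172) = 501.148, p = 1.8e-72
#>
#> Games-Howell pairwise comparisons:
#>  group1 group2      diff       se statistic     df     p_adj ...
#>  lesion   NAWM -0.046699 0.001882   -24.819  93.66 4.871e-10
#>  lesion    NWM -0.056525 0.002148   -26.318 114.87 5.373e-14
#>    NAWM    NWM -0.009826 0.001624    -6.051  94.38 8.681e-08
```

The recovered group means sit close to the simulated ground truths (NWM
9.9%, NAWM 8.5%, lesion 3.6%; one 7-subject cohort carries a between-subject
sampling SD of ~0.5 pp, so single-cohort means scatter around the truth).
The lesion and NAWM groups separate decisively from normal white matter, and
`autoplot(report)` draws the group comparison.

## Package layout

- `R/` — signal model, protocol design, Bloch simulation, phantom,
  quantification, statistics, I/O, plots
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/stair-epi-mwi.Rmd` — the methods vignette (model, assumptions,
  parameter choices, limitations)
- `inst/extdata/defaults.yaml` — default protocols, constants, calibrated
  pulse and phantom configuration
- `exec/stairmwi` — command-line wrapper
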