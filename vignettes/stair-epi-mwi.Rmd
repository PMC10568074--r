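---
title: "Quantifying myelin water with STAIR-EPI: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myelin water with STAIR-EPI: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairmwi)
```

## The signal model and its assumptions

Myelin water (MW) relaxes much faster than the other water pools in brain
tissue: T1 ≈ 220 ms and T2* ≈ 10 ms, against T1 ≈ 600–2000 ms and
T2* ≈ 60 ms for intra/extracellular water and CSF. A short-TR adiabatic
inversion-recovery (STAIR) acquisition exploits the T1 gap. Each cycle a 90°
excitation zeroes the longitudinal magnetization, it recovers for
TR − TI, an adiabatic full-passage (AFP) pulse scales it by the inversion
efficiency Q (−1 = perfect inversion, +1 = untouched), it recovers again for
TI, and is read out. The steady state of this cycle has the closed form

$$S_\mathrm{STAIR} = M_0\left(1 - Q e^{-TR/T_1} - (1-Q)\,e^{-TI/T_1}\right)
e^{-TE/T_2^*},$$

implemented in `stair_signal()`. The derivation assumes exactly 90°
excitation (the recursion then converges in a single cycle because every
excitation erases the longitudinal history); the functions therefore refuse
other flip angles instead of silently approximating. `steady_state_oracle()`
simulates the cycle explicitly and is held equivalent to the closed form to
1e−8 over a thousand random parameter draws in the test suite. Signals are
returned signed so null crossings are observable; magnitudes appear only
where the phantom models what a scanner records.

The proton-density (PD) reference is modeled as pure T2* decay,
$S_\mathrm{PD} = M_0 e^{-TE/T_2^*}$ (`pd_signal()`): its small excitation
angle makes the acquisition effectively proton-density-weighted, and TR and
flip angle are intentionally ignored by the model.

The model has no B1/B0 inhomogeneity terms (adiabatic inversion is robust to
both and the remaining factors cancel in the image ratio below), and no
magnetization transfer or exchange.

## Inversion-time design

With Q = −1 for long-T1 water, the pre-readout residual per unit $M_0$ is
$1 + e^{-TR/T_1} - 2e^{-TI/T_1}$. A single T1 can be nulled exactly at
$TI = -T_1 \ln\!\big((1 + e^{-TR/T_1})/2\big)$; a band of T1 values can only
be suppressed approximately. `optimal_ti()` minimizes the mean squared
residual over a uniform T1 grid on [600, 2000] ms (141 points, 10 ms
spacing). The objective form is a design choice — the original formulation
is not available in closed form — and was chosen because it reproduces the
published protocol value: at TR = 250 ms it gives TI = 116.73 ms (117 ms to
the nearest millisecond), with a worst-case band residual of 1.3% of $M_0$
at T1 = 600 ms. A minimax objective over the same grid is available
(`objective = "minimax"`); it lands near 114.5 ms and halves the worst-case
residual at the cost of the mean-squared one. The optimum is insensitive to
the grid spacing (< 0.5 ms between 10 ms and 2 ms grids) and is found by a
1 ms scan plus golden-section/parabolic refinement, which the tests hold to
within 0.02 ms of an exhaustive 0.01 ms search.

Repetition times between 180 and 300 ms give reasonable myelin-water
contrast per unit time; `suppression_spec()` warns outside that range and
`mw_contrast_vs_tr()` traces the trade-off.

## Why Q_MW = −0.75: Bloch simulation of the AFP pulse

The quantification assumes the 8.64 ms AFP pulse inverts long-T2 water
completely (Q = −1) but myelin water only partially, because T2* ≈ 10 ms is
comparable to the pulse duration and coherence decays mid-sweep. The pulse
shape is a hyperbolic secant (HS1) — the standard adiabatic full passage —
with β = 5, μ = 4.9 and 2048 waveform samples; only the duration is fixed by
the protocol, so the remaining shape parameters are package defaults.

`bloch_evolve()` integrates the Bloch equations with relaxation in the frame
rotating at the instantaneous RF frequency (effective field
$(\omega_1(t), 0, -\Delta\omega(t))$, on-resonance spins only), using
per-sample rotation followed by relaxation decay (operator splitting). A
fine-step RK4 integration of the same equations serves as the reference in
the tests; the splitting result also converges under grid doubling
(|Δq| < 1e−4 at 2048 samples) and conserves |M| to 1e−6 when relaxation is
switched off.

The peak amplitude is not a free dial: `calibrate_peak_b1()` fixes it as the
smallest amplitude on a 50 Hz grid for which Q(T1 = 1000 ms, T2 = 2000 ms)
≤ −0.98, anchoring the long-T2 limit *before* the myelin-water case is
evaluated. For the default shape this gives 700 Hz, a long-T2 plateau at
Q = −0.986 (insensitive to +25% amplitude), and Q(T1 = 220 ms, T2 = 10 ms)
= −0.836. That value sits within the ±0.10 band around the assumed −0.75;
exact agreement cannot be expected because the published protocol does not
specify the pulse's bandwidth or amplitude, and Q at short T2 depends on
both. `q_profile()` documents the monotone decline of Q with T2.

## From image pair to aMWF

Since the STAIR image at the optimal TI contains (to within the suppression
residual) only myelin-water signal and the PD image contains total water,

$$\mathrm{aMWF} = \frac{M_{0,\mathrm{MW}}}{M_{0,\mathrm{total}}}
= k\,\frac{S_\mathrm{STAIR}}{S_\mathrm{PD}},\qquad
k = \frac{e^{-TE_\mathrm{PD}/T_{2,\mathrm{total}}^*}}
{\big(1 - Q_\mathrm{MW} e^{-TR/T_{1,\mathrm{MW}}} -
(1-Q_\mathrm{MW})e^{-TI/T_{1,\mathrm{MW}}}\big)e^{-TE/T_{2,\mathrm{MW}}^*}}$$

with k ≈ 7.44 for the default protocols and constants (`amwf_scale_factor()`).
The "apparent" qualifier is earned: the estimator assumes fixed literature
constants (T1,MW = 220 ms, T2*,MW = 10 ms, T2*,total = 60 ms, Q_MW = −0.75)
and perfect long-T1 suppression, so residual leakage and constant
mis-specification bias the map.

Numerical choices in `compute_amwf_map()`: voxels whose PD signal falls
below 10% of the robust (99th-percentile) maximum are masked out rather than
producing unstable ratios, and only the largest connected component of the
threshold mask is kept; raw values are clipped to [0, 1] with the clipped
counts recorded (how sub-threshold and negative voxels were handled in the
original MATLAB pipeline is not documented, so the package makes its policy
explicit and configurable). The map is invariant to any common intensity
scaling of the two volumes.

## What the phantom emulates — and what it does not

The study this method was validated on deposited no image data, so the
package ships a digital phantom as its test bed. `build_label_map()` draws
an ellipsoidal brain with a cortical grey-matter shell, white-matter core,
central CSF, spherical lesions placed by seeded rejection sampling strictly
inside white matter, and eight white-matter analysis ROIs in lesion-free
tissue — a geometric stand-in for the eight manually drawn regions of the
in-vivo analysis, with no claim to anatomical fidelity.

Class ground truths: only the white-matter T1 range and the group aMWF
values (NWM 9.9%, NAWM 8.5%, lesion 3.6%) are anchored to published
measurements; the rest (GM and CSF aMWF, proton densities, long-pool T1s:
NWM 850 ms, NAWM 900 ms, GM 1500 ms, lesion 1100 ms, CSF 4000 ms) are
editorial defaults within physiological ranges, exposed in
`tissue_classes()` and the config file.

Two forward modes:

* `model_matched` — the voxel signal is exactly the single-pool model the
  quantifier inverts. Noise-free recovery is then exact to machine precision
  (a round-trip identity the tests enforce at 1e−10), which isolates
  noise-driven error from model error.
* `two_pool` — both compartments contribute to both acquisitions, including
  the long-T1 pool's leakage through the imperfect null. For NWM parameters
  this inflates the apparent value from 9.9% to ≈ 11.9%, a positive bias
  that shrinks as the long-pool T1 approaches the band's null crossing
  (~950 ms at TI = 117 ms) — the phantom's model of why the measured
  quantity is *apparent*.

Noise: each of the NEX excitations receives independent complex Gaussian
noise (SD `noise_sigma` per channel); the complex average is taken first and
then the magnitude, as a scanner does, giving a Rayleigh floor of
σ√(π/2)/√NEX where signal is absent and Rician bias where SNR is low. The
published protocol reports no SNR, so the default σ = 0.005 (in units where
CSF proton density is 1) was chosen once as realistic — PD white-matter SNR
≈ 128 per excitation and STAIR white-matter SNR ≈ 9 after NEX = 30
averaging, consistent with visibly clean averaged images — and not revisited.
At that level the only visible bias is the Rician floor in the low-SNR
lesion ROIs (≈ +0.15 pp).

Cohorts: `simulate_cohort()` draws 7 controls and 7 patients; each subject's
class aMWF values are jittered by a between-subject SD matching the reported
group SDs (1.3/1.2/1.3 pp for NWM/NAWM/lesion), truncated to [0, 0.5]. With
7 subjects that jitter leaves a sampling SD of ≈ 0.5 pp on a single cohort's
pooled group mean — so one simulated "study" scatters around the truth
exactly as a real 7-subject study would, and `recover_group_means()`
averages replicate cohorts when a tighter Monte Carlo estimate of the
recovery is wanted. A consequence worth knowing: the 1.4 pp NWM–NAWM gap is
about one between-subject SD, so a minority of simulated cohorts do not
reach p < 0.001 on that pair even though the pooled analysis always does.
Lesion separations (≈ 5 pp) are decisive in every cohort.

The phantom is generated in image space at a reduced 64 × 64 × 15 matrix
(1.72 × 1.72 × 5 mm voxels; the in-vivo matrix is 128 × 128 × 15 and is
available via the config): there is no EPI k-space model, so multi-shot
trajectory effects — ghosting, distortion, eddy currents — and coil
sensitivities and motion are outside what passing tests can certify. Passing
recovery tests show the estimator inverts its own forward model correctly at
realistic noise, and the two-pool mode bounds the leakage bias; they do not
validate the acquisition physics of a real scanner.

## Statistics

The group workflow mirrors a standard cross-sectional comparison:
Kolmogorov–Smirnov normality per group (Lilliefors-corrected by default,
since mean and SD are estimated from the sample; the uncorrected variant is
a flag), classical one-way ANOVA, Games–Howell pairwise post hoc (Welch
standard errors and degrees of freedom, studentized-range p-values via
`ptukey`, so unequal variances and sizes are handled), and t-based 95%
confidence intervals of group means. Observations are pooled across subjects
as given — ROI means and individual lesions — with no mixed-effects
correction for within-subject correlation; the report prints its n per group
so the unit of analysis is always visible. Under equal variances and sizes
the Games–Howell q statistic coincides with Tukey's HSD and the adjusted
p-values converge as the per-pair degrees of freedom grow; the family-wise
type-I error is calibrated at 0.05 ± 0.01 under 10⁴ null simulations at the
cohort's group sizes in the test suite.

## Problem sizes used in the shipped tests

The suite exercises the full 64 × 64 × 15 phantom where exactness is claimed
(round-trip identity), a 24 × 24 × 7 phantom for distributional checks, ten
replicate cohorts for parameter recovery, 200–1000 random draws for the
oracle equivalences, and 10⁴ simulations for the type-I-error and coverage
calibrations.

## Known limitations

* Q_MW from the Bloch module depends on unpublished pulse parameters; the
  package pins it by the long-T2 calibration rule and documents the ±0.10
  uncertainty rather than pretending to the exact −0.75.
* The aMWF estimator inherits every bias of its fixed constants and of
  residual long-T1 leakage; `two_pool` mode quantifies the latter only for
  the parameter ranges the phantom covers.
* The phantom's geometry and the GM/CSF/proton-density defaults are
  editorial; conclusions about absolute GM values or partial-volume effects
  should not be drawn from it.
* No registration between the STAIR and PD volumes is attempted — they are
  assumed co-registered, as they are when acquired back-to-back.
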