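# Default run configuration: in-vivo 3T whole-brain protocols, the fixed
# quantification constants, the calibrated adiabatic pulse and the
# desk-scale phantom. All times in milliseconds, amplitudes in Hz.
protocols:
  stair: {tr_ms: 250, ti_ms: 117, te_ms: 5.5, flip_deg: 90, nex: 30, label: STAIR-EPI}
  pd: {tr_ms: 250, te_ms: 5.5, flip_deg: 5, nex: 10, label: PD-EPI}
constants:
  t1_mw_ms: 220
  t2s_mw_ms: 10
  t2s_total_ms: 60
  q_mw: -0.75
  q_long: -1
  t1_suppress_lo_ms: 600
  t1_suppress_hi_ms: 2000
afp:
  shape_name: HS1
  duration_ms: 8.64
  beta: 5
  mu: 4.9
  n_samples: 2048
  # smallest amplitude on the 50 Hz calibration grid with Q(T2 = 2000 ms) <= -0.98
  peak_b1_hz: 700
phantom:
  shape: [64, 64, 15]
  voxel_mm: [1.72, 1.72, 5.0]
  n_lesions: 9
  lesion_radius_vox: [1.5, 3]
  n_rois: 8
  roi_radius_vox: 3
  noise_sigma: 0.005
  mode: model_matched
  seed: 1
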