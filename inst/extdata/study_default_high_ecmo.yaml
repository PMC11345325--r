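condition: high_ecmo
seed: 1
scene:
  positions:
  - ascending
  - distal_arch
  - mid_descending
  grid_spacing_mm: 2.0
  duration_s: 1.5
  dt_s: 0.0008
  start_offsets_s:
  - 0.0
  - 0.21
  - 0.37
  onset_s: 0.1
  gate_width_s: 0.3
  interface_halfwidth_mm: 4.0
  total_path_mm: 230.0
  flux_smooth_tau_s: 0.15
  vortices: default
pump:
  stroke_volume_ml: 30.0
  heart_rate_bpm: 90.0
  systole_fraction: 0.4
  ecmo_flow_lpm: 1.0
pressure:
  systolic_mmhg: 81.0
  diastolic_mmhg: 57.0
  bimodal: yes
  sample_rate_hz: 500.0
acquisition:
  center_frequency_hz: 5000000.0
  sound_speed_mps: 1540.0
  prf_hz: 10000.0
  tx_angles_deg:
  - -10.0
  - 10.0
  pairs_per_frame: 4.0
  noise_std_hz: 5.0
  iq_mode: no
analysis:
  cone_deg: 30.0
  speed_threshold_mps: 0.25
  min_speed_mps: 0.02
  systole_duration_s: 0.3
  onset_min_area_frac: 0.05
  mixing_bin_mm: 4.0
render:
  enabled: no
  style: dense-small
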