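geometry:
  mode: open_ring
  n_detectors_closed: 20
  ring_inner_diameter_mm: 418.0
  crystals_per_detector_row: 32
  crystal_pitch_mm: 2.09
  axial_extent_mm: 66.0
phantom:
  grid_n: 160
  grid_spacing_mm: 2.0
  mu_511kev_per_mm:
    air: 0.0
    water: 0.0096
    lucite: 0.0111
    head_analog: 0.01
    teflon: 0.0186
beam:
  energy_mev: 109.4
  dose_mu: 25.0
  entrance_position_mm: -100.0
  n_sheets: 1
  sheet_wet_mm: 6.8
  beam_sigma_mm: 4.5
  bragg_kleeman_a_cm: 0.0022
  bragg_kleeman_p: 1.77
  rsp:
    water: 1.0
    lucite: 1.16
    head_analog: 1.0
  proximal_ramp_mm: 2.0
  falloff_80_20_mm: 4.0
acquisition:
  duration_s: 60.0
  counts_per_mu: 92000.0
  energy_fwhm_frac: 0.272
  time_fwhm_ns: 9.2
  background_rate_per_s: 2000.0
  background_energy_kev:
  - 200.0
  - 700.0
  background_dt_halfwidth_ns: 20.0
  scatter_fraction: 0.0
  scatter_angle_sd_deg: 10.0
  scatter_energy_kev:
  - 250.0
  - 511.0
  positron_blur_sigma_mm: 0.0
  seed: 1
recon:
  grid_n: 160
  pixel_size_mm: 2.0
  n_subsets: 5
  n_iterations: 10
  nonneg_floor: 1.0e-12
  band_halfwidth_mm: 9.0
analysis:
  energy_window_kev:
  - 350.0
  - 650.0
  timing_full_width_ns: 20.0
  smooth_sigma_mm: 2.0
  refine_spacing_mm: 0.1
  edge_reference: peak
  shift_convention: distal_edge
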