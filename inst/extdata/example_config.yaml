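# Example rootrose run configuration (synthetic box).
boxes:
  - box_id: demo
    density: D3
    treatment: C
    replicate: 1
    sim:
      n_laterals: 8
daps: [12, 14, 19, 21, 26]
processing:
  gaussian_sigma: 0.6
  low_percentile: 50
  high_percentile: 85
  min_component_px: 20
  close_radius_px: 2
  intensity_gate: 0.08
geometry:
  gel_depth_mm: 33.0
  voxel_size_mm: 0.5
analysis:
  collapse_method: outer
  n_sectors: 16
  exclusion_radius_px: 1
render:
  psf_sigma: 0.5
  noise_sd: 0.02
  n_artifacts: 0
output_dir: demo_run
seed: 11
keep_images: true
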