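# Default pipeline configuration: three simulated islands, automated-count
# track with nearest-neighbour filtering and per-site calibration.
seed: 1
species: adeliae
output_dir: pengcensus-run
islands:
  n: 3
  extent: [0, 200, 0, 200]
  n_subcolonies: 4
  nests_per_subcolony: 150
  cluster_radius: 3
  hardcore: 0.7
render:
  gsd: 0.05
  artifact_intensity: 0.003
  blob_sigma: 0.12
  blob_amplitude: 1
  noise_sd: 0.02
detection:
  tile_size: 512
  halo: 16
  threshold: 0.08
  blob_scale: 0.12
  merge_radius: 0.35
filter:
  method: mixture
  k: 2
  m: 2
calibration:
  n_plots: 16
  plot_size: 20
  observer_cv: 0.01
  observer_bias: 1
census:
  interpretation: normal95
  n_reps: 100000
landsat:
  enabled: false
  scene_size: 64
  cell_size: 30
  noise_sd: 0.01
  spectra:
    guano: {green: 0.28, red: 0.32, nir: 0.35}
    nonguano: {green: 0.12, red: 0.14, nir: 0.18}
  offsets: {green: 0.02, red: -0.015, nir: 0.03}
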