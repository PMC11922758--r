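# Demo configuration for `hypoatlas run-all`: a small synthetic dataset
# with a planted 2x3 hierarchy, one simulated species pair, a planted
# spatial map and planted effector genes.
seed: 1
out_dir: hypoatlas_demo_out
hierarchy:
  levels: [2, 3]
  cells_per_leaf: 120
  embedding_dim: 10
  separation: 8.0
  noise_sd: 1.0
counts:
  n_genes: 150
  markers_per_leaf: 8
tree:
  resolutions: [0.05, 1.0]
  n_runs: 10
spatial:
  n_regions: 6
  spots_per_region: 40
effectors:
  n_genes: 2000
  n_celltypes: 12
  n_planted: 40
  top_n_genes: 200
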