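# Example pipeline configuration (schema version 1). Omitted fields fall back
# to the package defaults, which emulate the study conditions the pipeline was
# designed around.
config_version: 1
synthetic:
  seed: 1
  n_chromosomes: 2
  chromosome_length: 500000
  bin_width: 100
  n_background_genes: 300
  background_mean: 30
  dispersion: 20
  n_cuts: 60
  cut_length_range: [300, 1500]
  cut_fold_range: [12, 32]
  wt_cut_mean: 6.5
  depth_ratio: 1.3125
  contaminant_fraction: 0.1
caller:
  fold_threshold: 4
  min_consecutive_bins: 3
  noise_min_count: 10
  pseudocount: 1
  min_length: 200
options:
  region_width: 500
  log_base: 10
  scatter_pseudocount: 1
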