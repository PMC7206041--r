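# Demo run: fully synthetic, small enough to finish in seconds.
seed: 42
simulate:
  enabled: true
  n_genes: 500
  n_pathways: 20
  pathway_size_range: [10, 20]
  n_implanted_pathways: 3
  within_implanted_dysreg_frac: 0.5
  background_dysreg_frac: 0.05
  effect_mean: 2.5
  effect_sd: 0.4
  nb_dispersion: 0.1
  library_size_ratio: 1.3
  up_fraction: 0.5
  interactome:
    n_nodes: 200
    n_communities: 5
    community_size: 10
    p_in: 0.9
    p_out: 0.01
ssa:
  normalization: upper_quartile
  pseudocount: 0.5
  min_set_size: 5
deg:
  lfc_threshold: 1
network:
  score_min: 700
  expansion: first_shell
  hub_fraction: 0.10
  penalty: 2
  min_size: 3
  min_density: 0.5
  omega_threshold: 0.8
  alpha: 0.05
enrich:
  alpha: 0.05
  correction: none
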