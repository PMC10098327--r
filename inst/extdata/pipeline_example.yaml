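# Example configuration for run_pipeline(); unset keys take the defaults.
seed: 1
out_dir: results/pipeline
stages: [simulate, preprocess, scstar, omics]
sim:
  n_genes: 200
  n_cells_per_condition: {sham: 150, day1: 150}
  transition_genes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
  library_size_mean: 5000
qc:
  min_genes: 50
  n_hvg: 150
  n_pcs: 20
scstar:
  n_components: 8
omics:
  n_bulk: 120
  n_prot: 100
  n_overlap: 15
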