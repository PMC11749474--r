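input:
  simulate: true
qc:
  min_genes: 300
  max_genes: 6000
  max_mito: 0.1
  min_cells: 3
normalize:
  scale: 1000000
cluster:
  n_top_genes: 1500
  n_components: 20
  k_neighbors: 15
  resolution: 1.0
contrast:
  young_age: 2
  old_age: 19
  focal_type: NSC
seed: 1
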