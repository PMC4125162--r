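# Demo pipeline configuration (fully synthetic, small enough to run in
# seconds). Unset fields fall back to the protocol defaults: 19 km buffer,
# 50 stops, years 1998-2002, 3000 bootstrap replicates, 2000 trees.
seed: 42
output_dir: canopyrich-demo
buffer_radius: 450          # meters; inscribed in the 32x32 demo grids
simulate:
  n_routes: 24
  grid_rows: 32
  grid_cols: 32
survey:
  n_species_pool: 40
  effect_metrics: [ENTROPY, C.CWED]
  effect_sizes: [6.0, 4.0]
model:
  n_boot: 500               # full runs use 3000
  n_trees: 500              # full runs use 2000
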