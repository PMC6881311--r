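# Desk-scale run profile: one-CPU end-to-end run in minutes.
# Full-scale reference values: 128-px tiles on a 5 m grid, up to 4000
# tiles, a 5-level U-net, 20 epochs x 2500 steps (50,000 steps) at batch 16.
seed: 42
scene: {}
tiles:
  tile_px: 64
  grid_spacing_m: 2.0
  max_tiles: 220
augment: {}
model:
  levels: 4
  base_filters: 16
train:
  learning_rate: 1.0e-4
  epochs: 10
  steps_per_epoch: 80
  batch_size: 16
evaluate:
  threshold: 0.5
  aggregate: unweighted
map:
  tile_px: 64
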