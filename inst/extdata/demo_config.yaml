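# Demonstration pipeline configuration: a small synthetic stack and a
# reduced model so the full run completes on a laptop CPU in a few minutes.
seed: 7
output_dir: bundleseg_demo
synth:
  image_height_px: 256
  image_width_px: 256
  um_per_px: 20
  n_sections: 6
  n_bundles: 3
train:
  pretrain_epochs: 6
  te_epochs: 2
  patches_per_section: 6
  patch_size: 128
  batch_size: 8
  labeled_sections: [0, 1, 2]
  loss_weights:
    focal: 1.0
    contrastive: 0.05
model:
  base_width: 4
  depth: 3
  fc_sizes: [64, 32]
infer:
  threshold: 0.4
postprocess:
  min_area_mm2: 2.0
  min_border_dist_mm: 0.5
  max_dist_mm: 0.5
  downsample: 10
density:
  scope: section
evaluate:
  min_frac: 0.2
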