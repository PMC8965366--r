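# Full-width configuration matching the reference architecture: 128^3
# volumes, 64^3 patches at stride 32 (27 per volume), full channel widths.
# Provided as the canonical large-scale settings; training at this scale
# needs GPU-class hardware.
cohort_dir: cohort
output_dir: runs/full-scale
seed: 1
protocol: incomplete
k: 10
synthetic:
  volume_size: 128
  n_paired_per_class: 128
  n_unpaired_per_class: 52
  effect_size: 0.15
  noise_sd: 0.02
  missing_label_policy: imbalanced
stages:
  cycles: 3
  stage1:
    lr: 0.0005
    batch: 8
    l2: 0.001
    epochs: 30
  stage2:
    lr: 0.00001
    d_steps_per_g_step: 5
    patch_size: 64
    stride: 32
    epochs: 200
  stage3:
    lr: 0.0001
    epochs: 20
specs:
  generator:
    depth: 6
    width_scale: 1
  discriminator:
    depth: 6
    width_scale: 1
  fusion:
    branch_blocks: 3
    trunk_blocks: 2
    base_channels: 64
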