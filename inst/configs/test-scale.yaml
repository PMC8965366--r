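# Desk-scale configuration: 16^3 volumes, width scale 1/16, small epoch
# counts sized for a single CPU.
cohort_dir: cohort
output_dir: runs/test-scale
seed: 1
protocol: incomplete
k: 4
synthetic:
  volume_size: 16
  n_paired_per_class: 8
  n_unpaired_per_class: 4
  effect_size: 0.15
  noise_sd: 0.02
stages:
  cycles: 1
  stage1:
    epochs: 12
  stage2:
    epochs: 6
  stage3:
    epochs: 6
specs:
  generator:
    depth: 2
    width_scale: 0.0625
  discriminator:
    depth: 2
    width_scale: 0.0625
  fusion:
    branch_blocks: 2
    trunk_blocks: 1
    base_channels: 4
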