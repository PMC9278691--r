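# Example run configuration for run_pipeline() / the kbpdp wrapper.
# Every field is optional; package defaults fill the gaps.
seed: 1
n_plans: 10
out_size: 64
fractions: [0.64, 0.16, 0.20]
phantom:
  grid_size: 64
  n_ptvs: 3
  falloff_sigma: 6
  noise_sd: 60
model:
  use_attention: true
train:
  epochs: 120
  batch_size: 4
  learning_rate: 0.001
  patience: 30
evaluate:
  reference_dose: 70
  dvh_bin_width: 0.5
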