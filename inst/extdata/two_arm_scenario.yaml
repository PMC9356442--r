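# Example scenario configuration: the calibrated two-arm trial.
# Equivalent to recovery_two_arm(); edit rates/mix/schedule for variants.
arms: [standard_care, dexamethasone]
subgroups: [no_oxygen, oxygen_only, ventilated]
mortality:
  - [0.140, 0.178]
  - [0.262, 0.233]
  - [0.414, 0.293]
mix: [0.24, 0.60, 0.16]
block_size: 80
n_blocks: 100
metric_cut_fraction: 0.80
schedule:
  burn_in: 34
  cadence: 7
  lag: 28
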