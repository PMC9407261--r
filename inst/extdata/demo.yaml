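# Demo experiment config for the CLI `experiment` subcommand.
# A planted two-block network generated on the fly; flags override any key.
network:
  model: stochastic_block
  block_sizes: "30,30"
  p_within: "0.25"
  p_between: "0.02"
  seed: "2024"
train_fraction: 0.9
n_runs: 2
rfe_n_repeats: 1
rfe_n_trees: 50
no_tune: true
seed: 1
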