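# Example broad (stage-1) hyperparameter grid for tune_hyperparameters().
# Each entry is a set of model_config() overrides. Drop in your own file
# with the same layout to reproduce a larger search.
- hidden: 32
  learning_rate: 0.01
- hidden: 64
  learning_rate: 0.01
- hidden: 32
  learning_rate: 0.003
- hidden: 64
  learning_rate: 0.003
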