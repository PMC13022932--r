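{
  "n_rounds_max": 100,
  "n_bootstraps": 5,
  "val_fraction": 0.25,
  "test_fraction": 0.2,
  "batch_size": 10,
  "epochs_per_round": 1,
  "learning_rate": 0.001,
  "clients_per_round": 2,
  "patience": 20,
  "freeze_mode": "none",
  "selector": "best",
  "seed": 1
}
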