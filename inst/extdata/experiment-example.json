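{
  "cohort": {
    "n_samples": 1000,
    "n_continuous": 10,
    "n_binary": 10,
    "sparsity": 5,
    "signal_scale": 1,
    "label_noise": 0.05,
    "positive_fraction": 0.35,
    "seed": 1
  },
  "hp": { "psi": 1, "rho": 0.1 },
  "m": 5,
  "topology": "star",
  "partition_mode": "label_skew",
  "skew_alpha": 0.5,
  "test_fraction": 0.25,
  "checkpoints": [100, 200, 300, 400, 500, 600, 700, 800, 900, 1000],
  "local_epochs": 5,
  "methods": ["cpds", "fedavg", "local", "oracle"],
  "utility_kappa": 1,
  "cost_kind": "transmission",
  "record_every": 10,
  "seed": 1
}
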