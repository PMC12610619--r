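{
  "test_id": "ROCFimm",
  "family": "log",
  "terms": ["lnAge", "MPE", "lnAge:MPE"],
  "beta": {
    "(Intercept)": -4.64,
    "lnAge": 1.742,
    "MPE": -0.04,
    "lnAge:MPE": 0.025
  },
  "sigma": 0.79,
  "adj_r2": 0.414,
  "n_train": 668,
  "basis": {}
}
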