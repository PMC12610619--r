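{
  "test_id": "SVTT",
  "family": "log",
  "terms": ["lnAge", "MPE"],
  "beta": {
    "(Intercept)": -3.87,
    "lnAge": 1.352,
    "MPE": 0.053
  },
  "sigma": 0.702,
  "adj_r2": 0.2971,
  "n_train": 668,
  "basis": {}
}
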