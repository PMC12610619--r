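{
  "test_id": "ROCFcopy",
  "family": "quad",
  "terms": ["Age", "Age2", "MPE"],
  "beta": {
    "(Intercept)": -1.153,
    "Age": 10.398,
    "Age2": -2.912,
    "MPE": 0.019
  },
  "sigma": 0.586,
  "adj_r2": 0.4861,
  "n_train": 668,
  "basis": {}
}
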