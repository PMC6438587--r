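{
  "ring": {"J": 1, "gain": 4, "threshold": 0.5, "f0": 1, "tau": 10},
  "grid": {"n_points": 200},
  "noise": {"epsilon": 0.05, "a": 3, "b": 0.5},
  "stimulus": {"contrast": 2, "bias": 0},
  "duration": 100
}
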