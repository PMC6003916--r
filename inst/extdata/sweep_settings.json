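{
  "baseline": {
    "rho": 0.2,
    "r_l": 0.5,
    "r_min": 0.3
  },
  "high_threshold": {
    "rho": 0.2,
    "r_l": 0.5,
    "r_min": 0.7
  }
}
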