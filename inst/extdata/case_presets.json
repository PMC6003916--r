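{
  "climate": {
    "collapse_timescale_years": [30, 50],
    "recovery_timescale_years": 5000,
    "comment": "collapse triggering within decades under business-as-usual; recovery on a multi-millennial timescale (rho close to zero)"
  },
  "fisheries": {
    "collapse_timescale_years": 20,
    "recovery_timescale_years": 50,
    "comment": "stock collapse within about two decades; recovery generally exceeding decades"
  },
  "farming": {
    "collapse_timescale_years": 100,
    "recovery_timescale_years": 300,
    "comment": "land degradation over about a century; soil recovery up to centuries"
  }
}
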