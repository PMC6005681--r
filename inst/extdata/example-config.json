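{
  "cohort": {
    "n_animals": 2,
    "units_per_animal": [10, 10],
    "rates_hz": [64, 256],
    "n_sessions_per_rate": 2,
    "n_trials_per_session": 200,
    "seed": 1
  },
  "analysis": {
    "stages": ["behavior", "units", "decode", "efr", "stats"],
    "decoder_iterations": 25,
    "run_classifier": false
  }
}
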