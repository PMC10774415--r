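{
  "design": "ssc",
  "population_size": 1000,
  "generations": 20,
  "n_wt_females": 500,
  "n_wt_males": 250,
  "n_drive_males": 250,
  "seed": 42,
  "params": {
    "cleavage": 0.95,
    "hdr": 0.95,
    "r2": 0.99,
    "maternal_factor": 1.0
  }
}
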