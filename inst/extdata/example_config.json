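{
  "seed": 1,
  "out_dir": "fwaging-run",
  "stages": ["simulate", "score", "screen", "stepwise", "weights", "index"],
  "alpha_stay": 0.05,
  "weights_digits": 2,
  "signed_weights": false,
  "normalize": true,
  "family_care": "persons_per_household",
  "micro": { "n": 795, "item_noise": 1, "x_correlation": 0 },
  "macro": { "n_regions": 30, "years": [2005, 2010, 2015] }
}
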