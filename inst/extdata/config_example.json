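{
  "mdc_patho": 1.7,
  "mdc_as": 0.7,
  "clinical_threshold": 5.0,
  "alpha": 0.05,
  "seed": 1,
  "nonparametric": false
}
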