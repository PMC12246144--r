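{
  "n_patients": 8,
  "noise_cv": 0.2,
  "tetraspanin_mean_mfi": 4000,
  "protocol_noise_cv": 0.05
}
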