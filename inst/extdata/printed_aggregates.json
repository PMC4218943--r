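{
  "newborn": {
    "mean_mri_weight_g": 418,
    "mean_autopsy_weight_g": 434,
    "mean_absolute_difference_g": 20,
    "loa_low_g": -32,
    "loa_high_g": 65
  },
  "fetal": {
    "mean_mri_weight_g": 310,
    "mean_autopsy_weight_g": 312,
    "mean_absolute_difference_g": 5,
    "loa_low_g": -7,
    "loa_high_g": 12
  }
}
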