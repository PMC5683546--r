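# Reference hidden parameters fitted to the published aggregate outputs
# via ubt_calibrate(seed = 1) (multi-start bounded Levenberg-Marquardt on
# the shipped printed-target table). Regenerate with:
#   write_hidden_params(ubt_calibrate(seed = 1)$hidden, path)
uterotonic_efficacy: 0.45455075067462
presevere_fraction: 0.184312703763396
progression_prob: 0.013393566815902
surgery_access:
  home: 0.037550772262744
  clinic: 0.027419671378301
  hospital: 0.027414506570392
cfr_severe_no_surgery: 0.074925357379454
cfr_severe_surgery: 0.072475260512303
cfr_nonsevere_resolved: 0.001357066130722
nonatonic_death_load: 7464.994990390609928
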