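# Published aggregate outputs used as calibration targets.
# Tolerances encode the published precision (integer rounding on counts and
# percents; the severe-efficacy delta is printed "approximately 800").
# Weights are (observed/tolerance)^2 so the weighted relative-error objective
# equals the chi-square sum(((model - observed)/tolerance)^2).
# pct_gain_eff95 carries fit: false: in a one-pass cascade this percentage is
# an algebraic function of lives_saved and lives_saved_nonsevere and cannot be
# fitted independently; it is evaluated and reported as a model prediction.
targets:
- name: lives_saved
  observed: 6547
  tolerance: 0.5
  weight: 171452836
  fit: true
- name: pct_reduction
  observed: 11
  tolerance: 0.5
  weight: 484
  fit: true
- name: surgeries_averted
  observed: 10823
  tolerance: 0.5
  weight: 468549316
  fit: true
- name: anemia_averted
  observed: 634
  tolerance: 0.5
  weight: 1607824
  fit: true
- name: lives_saved_nonsevere
  observed: 1148
  tolerance: 0.5
  weight: 5271616
  fit: true
- name: severe_averted_nonsevere
  observed: 5287
  tolerance: 0.5
  weight: 111809476
  fit: true
- name: optimistic_delta
  observed: 800
  tolerance: 50
  weight: 256
  fit: true
- name: pct_gain_eff95
  observed: 10
  tolerance: 0.5
  weight: 400
  fit: false
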