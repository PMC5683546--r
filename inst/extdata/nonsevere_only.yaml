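# UBT withheld from cases already above 1000 mL; nonsevere pathway unchanged.
# Region and UBT blocks encode the published 2018 sub-Saharan Africa inputs.
name: nonsevere_only
region:
  live_births: 34806654
  setting_shares: {home: 0.50, clinic: 0.35, hospital: 0.15}
  pph_rate: {home: 0.12, clinic: 0.10, hospital: 0.08}
  atonic_fraction: 0.90
  year_label: "2018"
ubt:
  name: UBT
  penetration: {home: 0.0, clinic: 0.60, hospital: 0.80}
  utilization: {home: 0.0, clinic: 0.85, hospital: 0.85}
  efficacy_nonsevere: 0.85
  efficacy_severe: 0.70
ut_coverage: {home: 0.0, clinic: 0.60, hospital: 0.80}
scenario:
  filter: nonsevere_only
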