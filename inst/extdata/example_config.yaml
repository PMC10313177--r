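# Example run configuration for the tnbcqsp command-line front end.
population:
  n_patients: 50
  seed: 7
  diameter_median_cm: 1.65
  diameter_sdlog: 0.25
  seed_median_lung: 150
  seed_sdlog_lung: 0.8
  seed_median_other: 100
  seed_sdlog_other: 0.8
  max_burnin_days: 1500
regimen:
  dose_mg: 200
  interval_days: 21
trial:
  duration_days: 730
  assessment_interval: 63
  sd_min_days: 168
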