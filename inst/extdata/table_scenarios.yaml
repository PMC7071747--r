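# Four-scenario contamination study: clean, 5% at doubled mean, 5% at
# tripled mean, 10% at doubled mean.  Replicate count kept small here so the
# bundled file runs quickly; raise n_replicates (the reference study uses
# 1000) for publication-grade summaries.
defaults:
  n_population: 6000
  hr_per_unit: 1.25
  exposure_mean: 12
  exposure_sd: 8
  subcohort_size: 600
  n_replicates: 25
  seed: 20260101
  quantiles: [0.90, 0.95]
scenarios:
  - name: none
    contamination_fraction: 0
  - name: pct5_mean24
    contamination_fraction: 0.05
    contamination_mean: 24
  - name: pct5_mean36
    contamination_fraction: 0.05
    contamination_mean: 36
  - name: pct10_mean24
    contamination_fraction: 0.10
    contamination_mean: 24
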