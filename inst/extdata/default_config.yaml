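# Default icubench pipeline configuration: a 6-unit, 3-year synthetic
# registry at realistic university-ICU scale, benchmarked across all
# subgroups under the primary organ-donor policy.
simulate:
  n_units: 6
  years: [2015, 2016, 2017]
  admissions_per_unit_year: 1600
risk_model: saps2_logistic
subgroups:
  - NONTRAUMATIC_ICH
  - SAH
  - TBI_MULTITRAUMA
  - TBI_ISOLATED
  - NEURO_ALL
  - NON_NEURO
  - ALL
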