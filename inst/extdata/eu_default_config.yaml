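# Example EU-default run configuration.
# Monetary values are 2011 euros throughout; intakes are E% (percent of
# total energy). Disability weights are externally sourced from the
# published Global Burden of Disease 2010 weight tables (acute coronary
# event; post-event chronic ischaemic heart disease with mild/moderate
# sequelae) and are deliberately configured here rather than hard-coded.
inputs:
  synthetic:
    seed: 20110101
horizon_years: 85
discount_rate: 0.035
scenario: base
options: [reference, voluntary, labeling, legal_limit]
gdp_per_capita: 23300
decay_shape: linear
daly:
  disability_weight_acute: 0.422
  disability_weight_history: 0.08
  acute_duration: 1
psa:
  enabled: false
  n_draws: 1000
  seed: 20110101
  cost_se_frac: 0.2
  table_cv: 0.1
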