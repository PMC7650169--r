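# End-to-end pipeline configuration: simulated multi-site cohort of 1500
# over-50s whose analytic subset of 1010 carries the five ATN groups at
# 567/211/67/31/134 (see ?cohort_config for the combination-level defaults).
seed: 20260101
output_dir: pipeline_output
cohort:
  simulate: true
  config: {}          # cohort_config() defaults; seed is derived per stage
thresholds:
  abeta42: {method: fixed, value: 1025}
  ptau: {method: fixed, value: 24}
analyze:
  exposures: [apoe4_carrier, family_history, bmi]
  include_site: false
roc:
  contrasts: [alzheimers_disease]
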