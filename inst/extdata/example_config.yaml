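# Example generator configuration: a paper-shaped collection of
# 3 cohorts, 8 trials (16 arms) and 18 case-control studies under the
# default vulnerability model, with a mild interaction.
baseline_risk: 0.05
beta_L: 0.22314355131420976   # ln(1.25) per mmol/L among non-carriers
beta_GL: 0.13976194237515863  # ln(1.15) per mmol/L interaction
ldl_null: 3.5
allele_freq: 0.37
ldl_ref: 3.0
cohort_n: 12800
trial_n_per_arm: 3100
n_case_control: 18
seed: 1
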