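# Example trial configuration consumed by read_trial_config().
# Any omitted key keeps its package default; effect ratios and protocol
# fields override the defaults field by field.
n_per_arm: 20
cv_between: 0.40
cv_within: 0.25
cv_meas: 0.05
dropout_prob: 0.061
effect_ratio:
  isi: {CON: 1.0, DCON: 1.18, MED: 1.50, HED: 1.83}
  isr: {CON: 1.0, DCON: 1.3390, MED: 1.3667, HED: 1.2951}
weight_change: {CON: 0.0, DCON: -0.07, MED: -0.10, HED: -0.12}
protocol:
  basal_minutes: 120
  hyper_target_increment: 5.4
  square_wave_minutes: 15
  glp1_rate: 0.5
  arginine_dose_g: 5
  tracer_prime: 3.0
  tracer_infusion: 0.04
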