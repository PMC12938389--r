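# Example pipeline configuration (reduced sizes for a quick run).
# Keys mirror iatentropy::run_config() / cohort_spec().
cohort:
  n_exercise: 12
  n_nonexercise: 9
  effect_size_d: 1.0
  effect_conditions: [affective_incompatible]
  effect_regions: [frontal, fronto_central, central]
  n_trials_per_block: 8
  n_practice_per_block: 4
  sampling_rate_hz: 64
q: 0.05
protocol: repeated_split
target_rate_hz: 64
root_seed: 7
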