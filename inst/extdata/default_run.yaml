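# Default pipeline configuration: the 27-subject study composition.
seed: 42
device_scale: 100
noise_cv: 0.05
cutoffs:
  ricotem_minus_cutoff_pct: 25
  ricotem_plus_cutoff_pct: 50
cohort:
  controls: 7
  type1: 9
  mild_type1: 0
  type2a: 6
  type3: 2
  possible: 2
  hemophilia_mild: 1
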