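# Desk-scale example study configuration (see load_study_config()).
task: chest
counts:
  initial: [3, 0]
  retraining1: [3, 2]
  retraining2: [3, 2]
  test: [4, 3]
synthetic:
  grid_dim: 48
  noise_sd: 8
  lesion_diameter_range: [6, 14]
  annotators:
    - annotator_id: B01
      tier: board_certified
      sens_d50: 4.0
      fp_rate: 0.3
      centroid_jitter_sd: 0.5
    - annotator_id: R01
      tier: resident
      sens_d50: 5.5
      fp_rate: 0.8
      centroid_jitter_sd: 0.8
      distractor_confusion_prob: 0.25
detector:
  classifier: linear_baseline
  epochs: 6
  voi_edge: 16
integration:
  threshold_mm: 3.0
  strategies: [AND, OR, VOTING]
  cohorts: [all]
  combo_cap: 10
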