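# Demo pipeline configuration: a small synthetic cohort through every stage.
# Run with:  run_pipeline(system.file("extdata/demo_config.yaml",
#                                     package = "proteosubtype"), "demo_out")
seed: 7
simulate:
  n_samples: 48
  k_true: 4
  n_features: {mrna: 60, protein: 60, phospho: 40}
  n_plexes: 4
subtype:
  k: 4
  n_runs: 10
enrich:
  n_sets: 10
  n_kinases: 6
  n_perm: 200
stratify:
  min_tested: 25
  min_sensitive: 3
  sens_threshold: 100
model_drugs:
  model: en
  repeats: 1
  folds: 4
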