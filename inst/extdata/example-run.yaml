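# Example run config for the command-line interface:
#   elas simulate --config example-run.yaml --out out/
#   elas fit      --config example-run.yaml --out out/
#   elas evaluate --config example-run.yaml --out out/
master_seed: 1
output_dir: out
log_level: info
simulate:
  preset: table1-1y-death   # 4.6% positives at the published task size
  effect_size: 1.0
  censor_fraction: 0.1
labels:
  outcome: death
  horizon: 5
preprocess:
  variance_threshold: 0.01
  n_bins: 4
  bin_encoding: ordinal
elas:
  n_seed: 50
  n_batch: 10
  t_seed: 3
  k: 20
  n_folds: 5
  selection_metric: auroc
  learner:
    family: logreg_l2
    grid:
      - C: 1.0
      - C: 10.0
      - C: 100.0
evaluation:
  roster: [elas, base_logreg]
  n_repeats: 10
  test_fraction: 0.2
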