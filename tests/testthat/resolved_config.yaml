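simulate:
  'n': 100
  prevalence: 1.5
master_seed: 1
output_dir: '.'
log_level: info
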