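# Example run configuration for the command-line wrapper:
#   Rscript exec/lstar fit --config example_run.yaml --output out/
model: mr_lst_ar
spec:
  n_indicators: 3
  n_occasions: 4
  reference_rater: 1
simulate:
  n: 575
  params: example        # or a parameters YAML written by the package
  missingness: study     # study-like wave participation, or "none"
  seed: 1
bootstrap:
  B: 0                   # 0 = no confidence intervals
  level: 0.95
  seed: 1
output: lstar_run
seed: 1
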