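# Desk-scale run: 200k-subject synthetic registry, ~5.4% events,
# B = 2000 over the reduced event grid. Pass --paper-scale to valsize run
# (or set paper_scale = true) for the original design (B = 10000,
# events 5...1000).
seed = 42
out = valsize_out
n = 200000
n_covariates = 8
correlation = 0.2
beta = 0.24
baseline_shape = 1.1
censor_rate = 0.04
admin_horizon = 15
target_event_fraction = 0.054
shrinkage = 1
events = 10, 25, 50, 100, 200, 500
replicates = 2000
bootstrap_reps = 0
se_study = false
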