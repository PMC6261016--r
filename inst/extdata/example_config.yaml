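# Default pipeline configuration: simulate a two-class cohort and run the
# full analysis. Any key can be overridden; see ?validateConfig.
scenario: two_class_easy
out_dir: comirt_run
max_missing: 0.90
min_prev: 0.05
max_prev: 0.95
sample_fraction: 1.0
class_range: [1, 3]
discrimination: 1.7
n_starts: 4
max_iter: 300
tol: 1.0e-5
quadrature: 21
H_min: 0.3
max_errors: 1
monotonicity_alpha: 0.05
min_group_size: 50
subgroup_model: auto
characterization_alpha: 0.05
seed: 1
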