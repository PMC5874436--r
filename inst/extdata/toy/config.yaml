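# toy run configuration
drug_path: drugs.txt
sparsity_target: 0.97
association_threshold: 0.25
K_grid: [1, 2, 3]
top_n_terms: 15
review_fraction: 0.20
seed: 7
weighting: counts
n_restarts: 2
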