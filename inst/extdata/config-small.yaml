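# Small end-to-end run configuration: a desk-scale synthetic cohort pushed
# through every pipeline stage. Thresholds are the pipeline defaults.
out_dir: igem_small_run
seed: 7
K: 4
lambda_net: 0.5
lambda_W: 0.1
lambda_alpha: 0.1
lambda_H: 0.1
n_restarts: 2
max_iter: 300
rel_tol: 1.0e-6
sim:
  n_subjects: 90
  n_topics: 4
  n_genes: 90
  n_cpgs: 120
  n_snps: 200
  n_genesets: 12
  diff_frac: 0.3
  beta_effect: 0.05
  expr_effect: 1.0
  n_qtl: 4
  n_hwe_violations: 4
  missing_rate: 0.005
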