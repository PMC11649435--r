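# Example end-to-end scenario for run_pipeline(): a 65-sample cohort with a
# planted contraction of cluster NK_CD16, QC on simulated counts, clinical
# stratification, and DPA between conditions.
seed: 1
simulate:
  cluster_names: [NK_CD16, Tnaive_CD4, Tmem, Treg, NK_CD56]
  baseline_proportions: [0.10, 0.10, 0.30, 0.25, 0.25]
  effect_multipliers: [0.2, 2.2, 1.0, 1.0, 1.0]
  conditions: [normal, CKD]
  n_samples_per_condition: [42, 23]
  cells_per_sample: 150
  dirichlet_concentration: 200
  gene_model:
    n_genes: 500
    lowquality_cell_fraction: 0.1
qc:
  min_features: 200
  max_counts: 12000
  max_mito_pct: 30
stratify: [creatinine, egfr, age, sex]
dpa:
  w: 0.1
  iterations: 10000
  alpha: 0.05
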