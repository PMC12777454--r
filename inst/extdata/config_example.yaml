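# Example configuration for `Rscript recommender.R evaluate --config cfg.yaml`
cohort:
  patients_csv: data/patients.csv
  visits_csv: data/visits.csv
  prescriptions_csv: data/prescriptions.csv
method: cf_cosine          # cf_cosine | cf_euclidean | dr_rba_gower | dr_rbf | dr_nca
k_grid: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60]
n_outer: 5
n_inner: 5
seed: 42
scheme: equal              # equal | stability_heavy | burden_heavy
weighted: true             # similarity-weighted neighbour averaging
out_dir: run
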