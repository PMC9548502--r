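# tcrnodule

Peripheral-blood T-cell receptor (TCR) repertoire analysis for the
classification of indeterminate lung nodules.

Low-dose CT screening flags many lung nodules it cannot resolve: a large
fraction of patients sent to surgery turn out to have benign disease.
Tumour-driven clonal T-cell expansion leaves a measurable imprint on the
blood TCR repertoire — lower diversity, more hyperexpanded clonotypes —
which can complement imaging features such as the ground-glass-nodule
(GGN) phenotype. `tcrnodule` is aimed at immunogenomics and translational
researchers working with bulk CDR3&beta; clonotype tables (AIRR-style
TSVs) who want a tested, reproducible implementation of this analysis.

## What it computes

For each subject's clonal-fraction vector $p_1,\dots,p_S$:

* Shannon index $H=-\sum_i p_i\ln p_i$, Pielou evenness $H/\ln S$,
  clonality $1-H/\ln S$, Gini–Simpson index $1-\sum_i p_i^2$, and the
  read mass in five clonal-homeostasis bins (rare to hyperexpanded,
  thresholds $10^{-5},10^{-4},10^{-3},10^{-2}$ on the clonal fraction);
* benign/malignant group comparisons (Wilcoxon rank-sum) and Spearman
  feature–clinical correlations;
* group-exclusive clones, enriched CDR3&beta; sequences (union of
  per-subject top-30 and pooled top-3000, kept when shared by ≥ 2
  subjects) and their maximal common amino-acid motifs;
* feature ranking by random-forest importance and information gain, fused
  by mean rank;
* a support-vector-machine classifier whose kernel, cost $C$ and width
  $\gamma$ are tuned by a genetic algorithm maximizing stratified
  cross-validated AUC, with a Platt-calibrated predicted value and a
  Youden cutoff $\arg\max(\text{sensitivity}+\text{specificity}-1)$;
* ROC/AUC (rank statistic, half-credit ties), confusion metrics at the
  cutoff, and evaluations stratified by GGN, nodule size (≤ 20 mm,
  ≤ 10 mm) and stage.

A synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical structure this analysis assumes — heavy-tailed clone-size
spectra, reduced diversity in malignant subjects, public clones, a
plantable CDR3&beta; motif, correlated clinical covariates — so the whole
pipeline is testable without patient data.

## Worked example

Simulate a discovery cohort, profile it, select features, fit the
classifier and evaluate on an independent validation cohort:

```r
library(tcrnodule)

co   <- simulate_cohort(cohort_sim_config(n_benign = 25, n_malignant = 25,
                                          seed = 42))
prof <- diversity_profiles(co$repertoires)

compare_groups(prof, co$metadata, "shannon")[, c("median_a", "median_b",
                                                 "p_value")]
#>   median_a median_b p_value
#> 1     4.73     4.29 0.00901

tab <- assemble_features(prof, co$metadata)
sel <- select_top_features(rank_features(tab, seed = 1), 3)
fit <- ga_svm(reformulate(sel, "label"), tab,
              ga = ga_config(population_size = 15, generations = 10,
                             seed = 1))
fit
#> GA-tuned SVM nodule classifier
#> Features: evenness, ggn, clonality
#> Kernel rbf, C = 7352, gamma = 1.472
#> CV AUC 0.976; Youden cutoff 0.706 (J = 1.000)

va  <- simulate_cohort(cohort_sim_config(n_benign = 15, n_malignant = 15,
                                         seed = 99))
tva <- assemble_features(diversity_profiles(va$repertoires), va$metadata)
evaluation_report(predict(fit, tva), tva$label, cutoff = fit$youden_cutoff)
#> Evaluation (n = 30, positive = malignant)
#>   AUC 0.831; cutoff 0.706
#>   sens 0.533  spec 0.867  ppv 0.800  npv 0.650  acc 0.700
```

The benign group is more diverse (higher median Shannon index,
p ≈ 0.009); the selected feature triple couples the GGN flag with
entropy-based diversity; and the trained model transfers to the unseen
cohort with AUC 0.83. At the (training-derived) Youden cutoff the model
calls are conservative: four of five positive calls are correct
(PPV 0.80) at the cost of sensitivity. `run_pipeline()` wires these
stages together with on-disk artifacts and a hash manifest;
`read_clonotype_table()` / `read_metadata()` ingest real AIRR-style data
in place of the simulator.

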