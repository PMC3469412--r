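# modflux

Dynamic regulatory influence models for functional gene modules.

`modflux` builds cluster-level dynamic models of transcriptional
regulation from short time-course expression data, the setting typical of
*in vivo* preconditioning/stroke transcriptomics: a handful of genome-wide
snapshots (e.g. 3, 24, 72, 75, 96 h) under a few parallel treatment
conditions. Individual genes cannot be modeled dynamically at that
resolution, so the package works at the level of **functional modules** —
co-expressed gene clusters with coherent biological-process annotations —
and estimates the regulatory influences *between* them.

The workflow:

1. **Module discovery.** Hierarchical clustering (Ward's linkage) of log2
   fold-change profiles; the division (number of clusters) is selected by
   maximizing *functional coherence* — the number of genes annotated with
   at least one term significantly enriched (one-sided hypergeometric) in
   the gene's own cluster — swept over enrichment thresholds
   (`build_tree_and_cut`, `enrich_cluster`, `coherence_curve`).
2. **Steady-state inference.** A sparse influence model between cluster
   mean profiles by L1-penalized regression (each time point treated as an
   independent steady-state observation), one cross-validation fold per
   left-out treatment course, averaged and filtered into a starting matrix
   (`fit_target_lasso`, `infer_cv_models`, `consensus_initial_model`).
3. **Dynamics.** The model becomes a coupled linear ODE system
   `dc/dt = A c`, with influences off the diagonal and per-cluster decay
   `-1/τ` on it, solved in closed form with the matrix exponential and
   scored by gene-count-weighted correlation against observations
   (`simulate_trajectory`, `weighted_correlation_performance`).
4. **Calibration.** Two-stage simulated annealing (25 × 5000 steps at
   acceptance 0.80, then 25 × 25000 at 0.10, geometric cooling 0.002/step,
   relative perturbations `y·(1+f)`, `f ~ U(−0.6, 0.6)`, edge add/remove
   probabilities 0.001/0.01) against one observed course
   (`sa_config`, `optimize_two_stage`).
5. **Assessment.** Matrix-randomization nulls (resample / uniform /
   scramble; empirical and normal-tail p-values), validation against
   external gene–gene interaction sets via label-permutation nulls and
   TP/FN/TN/FP accuracy, and edge-wise comparison of condition-group
   consensus models (`significance_test`, `rewire_pvalues`,
   `validation_accuracy`, `group_consensus`, `compare_groups`).
6. **Synthetic data.** A generator with planted ground-truth models makes
   the whole pipeline testable offline (`generate_truth_model`,
   `generate_expression_dataset`, `generate_validation_data`), and
   `run_pipeline()` drives every stage from one YAML/list config with
   byte-reproducible artifacts.

## Worked example

Plant a 10-cluster influence model, simulate a noise-free five-treatment
dataset, perturb the true weights by ±50%, and let reduced two-stage
annealing recalibrate the matrix against the LPS course:

```r
library(modflux)

truth <- generate_truth_model(n_clusters = 10, edge_density = 0.1,
                              gene_counts = 20, seed = 42)
scenario <- synthetic_truth(truth, sigma_obs = 0, sigma_gene = 0, seed = 42)
data <- generate_expression_dataset(scenario)
course <- data$courses$lps

start <- truth
nz <- which(truth$A != 0)
set.seed(99)
start$A[nz] <- truth$A[nz] * (1 + runif(length(nz), -0.5, 0.5))

f0 <- weighted_correlation_performance(
  simulate_trajectory(start, course$observed[, 1], course$times),
  course, start$gene_counts)
cat(sprintf("fitness before calibration: %.3f\n", f0))

config <- sa_config(n_runs = 5, steps_stage1 = 2000, steps_stage2 = 5000,
                    seed = 7)
result <- optimize_two_stage(start, course, config)
cat(sprintf("fitness after calibration:  %.3f\n", result$best_fitness))

null <- significance_test(result$best_model, course, mode = "scramble",
                          n_reps = 100, seed = 31)
cat(sprintf("scramble null: mean %.3f, sd %.3f, empirical p %.4f\n",
            null$null_mean, null$null_sd, null$empirical_p))
```

Output:

```
fitness before calibration: 0.833
fitness after calibration:  1.000
scramble null: mean -0.012, sd 0.175, empirical p 0.0099
```

The weight perturbation costs about 0.17 of weighted correlation; the
annealer recovers an essentially perfect simulator of its training course,
and the recalibrated matrix beats all 100 structure-scrambled variants
(smoothed empirical p = 1/101). The fitness is the gene-count-weighted
mean of per-cluster Pearson correlations between simulated and observed
trajectories over the five observation times, simulated from the first
time point only.

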