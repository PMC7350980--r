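# panimpute

Imputation of an entirely missing gene-expression block from DNA methylation,
with transfer learning across cohorts.

## The problem

In multi-omics cancer studies, many samples carry high-quality DNA-methylation
profiles but no RNA-seq ("block missingness": the whole expression modality is
absent for a sample, not scattered cells of a matrix). Because promoter and
gene-body methylation regulate transcription, the missing expression matrix
can be predicted from the methylation matrix. Single-cohort predictors
struggle when few paired samples are available, which is exactly the regime
in which imputation is needed.

`panimpute` implements a pan-cohort transfer-learning imputer and everything
needed to evaluate it:

* **Neural imputer** — a fully connected network `beta values → sigmoid hidden
  layer → sigmoid output → min-max–inverted log2 expression`, trained by
  mini-batch Adam on the root-mean-square error per sample over genes,

  RMSE(y, y⁰) = sqrt( (1/N) Σᵢ (yᵢ − y⁰ᵢ)² ),

  where y is the predicted and y⁰ the measured expression vector and N the
  number of genes. Three variants: `transfer` (pretrain on the pooled
  reference cohorts with the target excluded, then fine-tune all layers on
  the target's available paired samples), `self` (train on the target only),
  `pretrain` (apply the pan-cohort model directly).
* **Baseline imputers** — per-gene mean, iterative truncated-SVD matrix
  completion on the concatenated `[methylation | expression]` matrix,
  kNN-weighted trans-omics imputation (inverse-distance weights in
  methylation space), and per-gene lasso regression (glmnet).
* **Evaluation suite** — per-sample RMSE/MAE/R²; preservation of the
  strongest CpG–gene correlations; recovery of methylation-driving genes
  (R² ≥ 0.5, BH q ≤ 0.05) and of prognosis-related genes (univariate Cox
  p ≤ 0.05) by average precision, top-100 overlap and enrichment factor;
  K-means clustering concordance (adjusted Rand index); ridge-Cox survival
  prediction (Harrell C-index); Kaplan–Meier curves with the log-rank test.
* **Synthetic multi-cohort generator** — seeded cohorts with a shared sparse
  CpG→gene mapping, cohort-specific weight magnitudes and baseline
  (tissue-of-origin) expression shifts, Beta-distributed methylation,
  sigmoid-warped nonlinear links, and proportional-hazards survival with
  calibrated censoring; planted driving pairs and prognosis genes serve as
  ground truth.
* **Benchmark orchestrator and CLI** — `benchmark_run()` executes any method
  subset over a missing-rate × replicate grid on identical partitions;
  `run_experiment()` drives the whole pipeline from a YAML config
  (`inst/scripts/panimpute-benchmark.R` is a thin command-line wrapper).

## Worked example

```r
library(panimpute)

gen <- generate_multi_cohort(synthetic_config(seed = 65))   # 4 cohorts x 200 samples
net <- network_config(input_dim = 500, output_dim = 300, hidden_dim = 64,
                      learning_rate = 1e-3, seed = 65)

pre  <- pretrain_pan_cancer(gen$cohorts, "C1", net)          # C1 excluded
plan <- make_missingness_plans(gen$cohorts[[1]], 0.9, 1, base_seed = 6500)[[1]]
truth <- gen$cohorts[[1]]$expression[plan$test_ids, ]

for (v in c("transfer", "self", "pretrain")) {
  imp <- run_variant(v, gen$cohorts, "C1", plan, net, pretrained = pre)
  cat(sprintf("%-9s RMSE %.3f\n", v, imputation_metrics(imp, truth)$rmse))
}
```

```
transfer  RMSE 0.433
self      RMSE 0.472
pretrain  RMSE 0.549
```

At 90 % missingness only 20 paired samples remain. Training on them alone
(`self`, 0.472) barely beats copying gene means; the pan-cohort model alone
(`pretrain`, 0.549) suffers from the target cohort's baseline expression
shifts it has never seen. Fine-tuning the pretrained model on those same 20
samples (`transfer`, 0.433) repairs the baselines while keeping the pooled
CpG→gene mapping — the transfer-learning advantage the package is built
around. The noise floor of this generator configuration is 0.3.

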