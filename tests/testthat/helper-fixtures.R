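# Small in-code fixtures shared across test files.

# a tiny deterministic omics matrix
tiny_matrix <- function(n = 3, p = 2, seed = 1, prefix = "f") {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n * p), 6), n, p)
    omics_matrix(m,
                 sample_ids = sprintf("s%d", seq_len(n)),
                 feature_ids = sprintf("%s%d", prefix, seq_len(p)))
  })
}

# a small synthetic cohort set for pipeline tests
small_cohorts <- function(seed = 42, n_cohorts = 3, n = 40, n_cpg = 30,
                          n_gene = 20, n_driving = 8, n_prog = 4) {
  cfg <- synthetic_config(n_cohorts = n_cohorts, samples_per_cohort = n,
                          n_cpg = n_cpg, n_gene = n_gene,
                          n_driving_pairs = n_driving,
                          n_prognosis_genes = n_prog, seed = seed)
  generate_multi_cohort(cfg)
}

# small network config suited to the desk-scale fixtures
small_net <- function(n_cpg, n_gene, hidden = 8, epochs = 20, lr = 1e-2, seed = 1) {
  network_config(input_dim = n_cpg, output_dim = n_gene, hidden_dim = hidden,
                 learning_rate = lr, pretrain_epochs = epochs,
                 finetune_epochs = max(epochs %/% 2, 1),
                 pretrain_batch = 16, finetune_batch = 8, seed = seed)
}

# hand-rolled survival table for oracle tests
toy_survival <- function() {
  survival_records(sprintf("s%d", 1:6),
                   time = c(5, 8, 12, 20, 33, 40),
                   event = c(1, 1, 0, 1, 1, 0))
}
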