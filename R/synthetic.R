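#' Configuration for the multi-cohort synthetic data generator
#'
#' The generator emulates the statistical structure the imputer targets:
#' several cohorts share a sparse CpG-to-gene regulatory mapping with
#' cohort-specific deviations, methylation beta values are Beta-distributed
#' with cohort-shifted means, driving genes respond to a sigmoid-warped
#' function of their driver CpG (so the mapping is nonlinear), and survival
#' times follow a proportional-hazards model driven by a designated gene
#' subset with uniform censoring.
#'
#' @param n_cohorts number of cohorts (default 4).
#' @param samples_per_cohort samples per cohort (default 200).
#' @param n_cpg CpG sites (default 500).
#' @param n_gene genes (default 300).
#' @param n_driving_pairs genes with a planted driver CpG (default 50).
#' @param shared_fraction mixing weight alpha in \[0, 1\] between the shared
#'   and the cohort-specific mapping weights (default 0.8); higher values
#'   mean more cross-cohort transferable structure.
#' @param effect_size scale of the driver effect on expression (default 3).
#' @param noise_sd Gaussian noise sd on log2-scale expression (default 0.3).
#' @param baseline_shift_sd sd of the cohort-specific per-gene baseline
#'   expression offset (default 0.3, log2 units) — the tissue-of-origin
#'   shift that dominates differences between real cohorts and that
#'   fine-tuning adapts to.
#' @param n_prognosis_genes genes driving survival (default 20, drawn from
#'   the driving genes so the survival signal is recoverable from
#'   methylation-based imputations).
#' @param hazard_coef log-hazard per sd of the standardized risk covariate
#'   (default 1).
#' @param censor_rate target censoring fraction in \[0, 1) (default 0.3).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_cohorts = 4, samples_per_cohort = 200,
                             n_cpg = 500, n_gene = 300,
                             n_driving_pairs = 50, shared_fraction = 0.8,
                             effect_size = 3, noise_sd = 0.3,
                             baseline_shift_sd = 0.3,
                             n_prognosis_genes = 20, hazard_coef = 1,
                             censor_rate = 0.3, seed = 1L) {
  for (nm in c("n_cohorts", "samples_per_cohort", "n_cpg", "n_gene")) {
    stop_if_not_scalar_number(get(nm), nm, min = 1)
  }
  if (n_driving_pairs > n_gene) stop("`n_driving_pairs` exceeds `n_gene`", call. = FALSE)
  if (n_driving_pairs > n_cpg) stop("`n_driving_pairs` exceeds `n_cpg`", call. = FALSE)
  if (n_prognosis_genes > n_gene) stop("`n_prognosis_genes` exceeds `n_gene`", call. = FALSE)
  stop_if_not_scalar_number(shared_fraction, "shared_fraction", 0, 1)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (baseline_shift_sd < 0) stop("`baseline_shift_sd` must be >= 0", call. = FALSE)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 samples_per_cohort = as.integer(samples_per_cohort),
                 n_cpg = as.integer(n_cpg), n_gene = as.integer(n_gene),
                 n_driving_pairs = as.integer(n_driving_pairs),
                 shared_fraction = shared_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_shift_sd = baseline_shift_sd,
                 n_prognosis_genes = as.integer(n_prognosis_genes),
                 hazard_coef = hazard_coef, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# sigmoid warp of a beta value around 0.5: the nonlinearity that gives the
# network a representable advantage over linear per-gene regression
warp_beta <- function(beta) 1 / (1 + exp(-6 * (beta - 0.5)))

#' Generate paired multi-cohort methylation/expression/survival data
#'
#' Methylation: per-CpG shared mean in U(0.2, 0.8) plus a cohort shift
#' N(0, 0.05), sampled from a Beta distribution with concentration 2 (broad,
#' near-bimodal beta values, as CpG data show). Expression (log2-like
#' scale): each driving gene g with driver CpG j follows
#' `baseline_g + effect_size * w_cg * warp(beta_j) + N(0, noise_sd)` with
#' `w_cg = alpha * w_shared + (1 - alpha) * w_cohort`; non-driving genes are
#' baseline plus noise; values are clipped at 0. Survival: exponential times
#' with log-hazard `hazard_coef * z` where z is the per-cohort standardized
#' mean expression of the prognosis genes; censoring is uniform with its
#' upper bound calibrated so the censoring fraction approximates
#' `censor_rate`.
#'
#' @param config a `synthetic_config`.
#' @return list with `cohorts` (list of `paired_cohort`) and `truth`
#'   (`driving_pairs` data.frame, `prognosis_genes`, per-cohort `weights`).
#' @export
generate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cpg_ids <- sprintf("cg%05d", seq_len(config$n_cpg))
  gene_ids <- sprintf("g%05d", seq_len(config$n_gene))
  with_rng_seed(config$seed, {
    driving_genes <- sort(sample(gene_ids, config$n_driving_pairs))
    driver_cpgs <- sample(cpg_ids, config$n_driving_pairs)
    n_prog_from_driving <- min(config$n_prognosis_genes, config$n_driving_pairs)
    prognosis_genes <- sort(sample(driving_genes, n_prog_from_driving))
    if (config$n_prognosis_genes > n_prog_from_driving) {
      extra <- sample(setdiff(gene_ids, driving_genes),
                      config$n_prognosis_genes - n_prog_from_driving)
      prognosis_genes <- sort(c(prognosis_genes, extra))
    }
    cpg_mean <- stats::runif(config$n_cpg, 0.2, 0.8)
    baseline <- stats::runif(config$n_gene, 2, 8)
    w_shared <- stats::runif(config$n_driving_pairs, 0.5, 1.5) *
      sample(c(-1, 1), config$n_driving_pairs, replace = TRUE)
    cohorts <- vector("list", config$n_cohorts)
    weights <- vector("list", config$n_cohorts)
    for (c_idx in seq_len(config$n_cohorts)) {
      cid <- sprintf("C%d", c_idx)
      n <- config$samples_per_cohort
      sample_ids <- sprintf("%s_S%04d", cid, seq_len(n))
      mu <- pmin(pmax(cpg_mean + stats::rnorm(config$n_cpg, 0, 0.05), 0.05), 0.95)
      kappa <- 2
      meth <- matrix(stats::rbeta(n * config$n_cpg,
                                  shape1 = rep(mu * kappa, each = n),
                                  shape2 = rep((1 - mu) * kappa, each = n)),
                     nrow = n, ncol = config$n_cpg,
                     dimnames = list(sample_ids, cpg_ids))
      # cohort-specific magnitudes keep the shared sign: a repressive CpG
      # stays repressive across cohorts, only its strength varies
      w_cohort <- stats::runif(config$n_driving_pairs, 0.5, 1.5) * sign(w_shared)
      w <- config$shared_fraction * w_shared +
        (1 - config$shared_fraction) * w_cohort
      # tissue-of-origin baseline shift: each cohort expresses every gene at
      # its own offset around the shared baseline
      base_c <- baseline + stats::rnorm(config$n_gene, 0, config$baseline_shift_sd)
      expr <- matrix(rep(base_c, each = n), nrow = n, ncol = config$n_gene,
                     dimnames = list(sample_ids, gene_ids))
      for (d in seq_len(config$n_driving_pairs)) {
        g <- driving_genes[d]
        expr[, g] <- expr[, g] +
          config$effect_size * w[d] * warp_beta(meth[, driver_cpgs[d]])
      }
      expr <- expr + matrix(stats::rnorm(n * config$n_gene, 0, config$noise_sd),
                            n, config$n_gene)
      expr <- pmax(expr, 0)
      z <- as.vector(scale(rowMeans(expr[, prognosis_genes, drop = FALSE])))
      event_time <- stats::rexp(n, rate = exp(config$hazard_coef * z) / 1000)
      if (config$censor_rate == 0) {
        time <- pmax(event_time, 0.5)
        event <- rep(1L, n)
      } else {
        v <- stats::runif(n)
        cens_frac <- function(cmax) mean(v * cmax < event_time)
        cmax <- stats::uniroot(function(cm) cens_frac(cm) - config$censor_rate,
                               lower = 1e-6, upper = 1e9, tol = 1e-6)$root
        cens_time <- v * cmax
        time <- pmax(pmin(event_time, cens_time), 0.5)
        event <- as.integer(event_time <= cens_time)
      }
      surv <- survival_records(sample_ids, time, event)
      cohorts[[c_idx]] <- structure(list(cohort_id = cid,
                                         methylation = meth,
                                         expression = expr,
                                         survival = surv),
                                    class = "paired_cohort")
      weights[[cid]] <- stats::setNames(w, driving_genes)
    }
    truth <- structure(list(driving_pairs = data.frame(gene_id = driving_genes,
                                                       cpg_id = driver_cpgs,
                                                       stringsAsFactors = FALSE),
                            prognosis_genes = prognosis_genes,
                            weights = weights),
                       class = "ground_truth")
    list(cohorts = cohorts, truth = truth)
  })
}

#' Binary label vectors for the planted gene sets
#'
#' @param truth a `ground_truth` from [generate_multi_cohort()].
#' @param gene_universe ordered character vector of gene ids; all truth genes
#'   must be present.
#' @return list with named 0/1 vectors `driving_labels`, `prognosis_labels`
#'   aligned to `gene_universe`.
#' @export
label_vectors <- function(truth, gene_universe) {
  known <- c(truth$driving_pairs$gene_id, truth$prognosis_genes)
  missing <- setdiff(known, gene_universe)
  if (length(missing)) {
    stop("truth genes absent from universe: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(driving_labels = stats::setNames(
         as.integer(gene_universe %in% truth$driving_pairs$gene_id), gene_universe),
       prognosis_labels = stats::setNames(
         as.integer(gene_universe %in% truth$prognosis_genes), gene_universe))
}

#' Write the planted ground truth as delimited tables
#'
#' `driving_pairs.tsv` (gene id, CpG id) and `prognosis_genes.tsv`.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(truth$driving_pairs, file.path(dir, "driving_pairs.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene_id = truth$prognosis_genes),
                     file.path(dir, "prognosis_genes.tsv"), sep = "\t")
  invisible(dir)
}
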