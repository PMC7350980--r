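#' Names of the available imputation methods
#' @return character vector of method names accepted by [benchmark_run()].
#' @export
all_benchmark_methods <- function() {
  c("transfer", "self", "pretrain", "mean", "svd", "tobmi", "lasso")
}

#' Names of the available evaluation metrics
#' @return character vector of metric names accepted by [benchmark_run()].
#' @export
all_benchmark_metrics <- function() {
  c("rmse", "mae", "sample_r2", "top_pair_r2", "driving_prauc", "driving_overlap",
    "prognosis_prauc", "prognosis_overlap", "enrichment_factor", "ari", "cindex",
    "logrank_p")
}

# impute the plan's test samples with one method; returns test x gene matrix
impute_with_method <- function(method, cohorts, target, plan, net_config,
                               base_config, pretrained) {
  train_meth <- target$methylation[plan$train_ids, , drop = FALSE]
  train_expr <- target$expression[plan$train_ids, , drop = FALSE]
  test_meth <- target$methylation[plan$test_ids, , drop = FALSE]
  switch(method,
    transfer = ,
    self = ,
    pretrain = run_variant(method, cohorts, target$cohort_id, plan, net_config,
                           pretrained = pretrained),
    mean = mean_impute(train_expr, plan$test_ids),
    svd = {
      all_ids <- c(plan$train_ids, plan$test_ids)
      expr_na <- rbind(train_expr,
                       matrix(NA_real_, length(plan$test_ids), ncol(train_expr),
                              dimnames = list(plan$test_ids, colnames(train_expr))))
      imputed <- suppressWarnings(
        svd_impute(target$methylation[all_ids, , drop = FALSE], expr_na, base_config))
      imputed[plan$test_ids, , drop = FALSE]
    },
    tobmi = tobmi_impute(train_meth, train_expr, test_meth, k = base_config$tobmi_k),
    lasso = lasso_impute(train_meth, train_expr, test_meth,
                         lambda = base_config$lasso_lambda, seed = base_config$seed),
    stop("unknown method: ", method, call. = FALSE)
  )
}

# all requested downstream metrics for one imputed test block
cell_metrics <- function(imputed_test, target, plan, metrics, assoc_full,
                         screen_full, top_prog_genes, reference_gene_list, seed) {
  truth_test <- target$expression[plan$test_ids, , drop = FALSE]
  out <- list()
  if (any(c("rmse", "mae", "sample_r2") %in% metrics)) {
    acc <- suppressWarnings(imputation_metrics(imputed_test, truth_test))
    out <- c(out, acc[intersect(c("rmse", "mae", "sample_r2"), metrics)])
  }
  needs_recon <- any(c("top_pair_r2", "driving_prauc", "driving_overlap",
                       "prognosis_prauc", "prognosis_overlap", "enrichment_factor",
                       "ari", "cindex", "logrank_p") %in% metrics)
  if (!needs_recon) return(out)
  # reconstructed dataset: observed training rows + imputed test rows
  recon <- target$expression
  recon[plan$test_ids, ] <- imputed_test[plan$test_ids, ]
  if ("top_pair_r2" %in% metrics) {
    out$top_pair_r2 <- suppressWarnings(
      top_pairs_mean_r2(assoc_full, target$methylation, recon))
  }
  if (any(c("driving_prauc", "driving_overlap") %in% metrics)) {
    assoc_imp <- cpg_gene_association(target$methylation, recon)
    rec <- driving_gene_recovery(assoc_full, assoc_imp)
    if ("driving_prauc" %in% metrics) out$driving_prauc <- rec$prauc
    if ("driving_overlap" %in% metrics) out$driving_overlap <- rec$overlap
  }
  needs_screen <- any(c("prognosis_prauc", "prognosis_overlap", "enrichment_factor",
                        "ari", "cindex", "logrank_p") %in% metrics)
  if (needs_screen) {
    screen_imp <- prognosis_gene_screen(recon, target$survival)
    if (any(c("prognosis_prauc", "prognosis_overlap", "enrichment_factor") %in% metrics)) {
      rec <- prognosis_gene_recovery(screen_full, screen_imp,
                                     reference_gene_list %||% character(0))
      if ("prognosis_prauc" %in% metrics) out$prognosis_prauc <- rec$prauc
      if ("prognosis_overlap" %in% metrics) out$prognosis_overlap <- rec$overlap
      if ("enrichment_factor" %in% metrics) out$enrichment_factor <- rec$enrichment_factor
    }
    if (any(c("ari", "logrank_p") %in% metrics)) {
      cc <- cluster_concordance(recon, target$expression, top_prog_genes, k = 2,
                                seed = seed)
      if ("ari" %in% metrics) out$ari <- cc$ari
      if ("logrank_p" %in% metrics) {
        lr <- suppressWarnings(km_logrank(target$survival, cc$labels_imputed))
        out$logrank_p <- lr$p
      }
    }
    if ("cindex" %in% metrics) {
      sig <- screen_imp$gene_id[screen_imp$flag]
      sm <- survival_model_eval(recon, target$survival, sig, penalty = "cv",
                                seed = seed)
      out$cindex <- sm$cindex
    }
  }
  out
}

#' Run the full method-by-missing-rate benchmark grid on one target cohort
#'
#' For every (missing rate, replicate) a seeded train/test partition is
#' built; every requested method imputes the identical partition; every
#' requested metric is computed against the held-out truth (accuracy metrics
#' on the test block, downstream metrics on the reconstructed dataset whose
#' test rows are imputed). Per-cell failures are recorded and the run
#' continues. The pan-cohort model is pretrained once and shared by the
#' `transfer` and `pretrain` variants across all cells, since pretraining
#' does not depend on the partition.
#'
#' @param cohorts list of `paired_cohort` objects.
#' @param target_id the cohort whose expression block is made missing.
#' @param methods subset of
#'   `c("transfer","self","pretrain","mean","svd","tobmi","lasso")`.
#' @param missing_rates fractions in (0, 1); default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param n_replicates partitions per rate (default 5).
#' @param seed master seed; all partitioning, training and fold seeds derive
#'   from it.
#' @param reference_gene_list external prognosis gene ids for the enrichment
#'   factor (optional).
#' @param net_config `network_config` for the neural variants; default
#'   is built from the data dimensions.
#' @param base_config `baseline_config` for the baseline imputers.
#' @param metrics metric names to compute (default: all).
#' @return object of class `"evaluation_report"`: list with `cells` (long
#'   data.frame: method, missing_rate, replicate, metric, value), `summary`
#'   (mean and sd over replicates) and `errors`.
#' @export
benchmark_run <- function(cohorts, target_id,
                          methods = all_benchmark_methods(),
                          missing_rates = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          n_replicates = 5,
                          seed = 1L,
                          reference_gene_list = NULL,
                          net_config = NULL,
                          base_config = baseline_config(seed = seed),
                          metrics = all_benchmark_metrics()) {
  stopifnot(all(methods %in% all_benchmark_methods()),
            all(metrics %in% all_benchmark_metrics()),
            all(missing_rates > 0 & missing_rates < 1))
  ids <- vapply(cohorts, function(co) co$cohort_id, character(1))
  target <- cohorts[[match(target_id, ids)]]
  if (is.null(net_config)) {
    net_config <- network_config(input_dim = ncol(target$methylation),
                                 output_dim = ncol(target$expression),
                                 seed = seed)
  }
  needs_pretrain <- any(c("transfer", "pretrain") %in% methods)
  pretrained <- if (needs_pretrain) {
    pretrain_pan_cancer(cohorts, target_id, net_config)
  } else NULL

  # full-data anchors, computed once
  assoc_full <- cpg_gene_association(target$methylation, target$expression)
  screen_full <- prognosis_gene_screen(target$expression, target$survival)
  top_prog_genes <- screen_full$gene_id[order(screen_full$p, screen_full$gene_id)]
  top_prog_genes <- top_prog_genes[seq_len(min(100L, length(top_prog_genes)))]

  cells <- list()
  errors <- list()
  for (r_idx in seq_along(missing_rates)) {
    rate <- missing_rates[r_idx]
    plans <- make_missingness_plans(target, rate, n_replicates,
                                    base_seed = seed + 1000L * r_idx)
    for (rep_idx in seq_len(n_replicates)) {
      plan <- plans[[rep_idx]]
      cell_seed <- seed + 1000L * r_idx + rep_idx
      for (method in methods) {
        res <- tryCatch({
          imp <- impute_with_method(method, cohorts, target, plan,
                                    net_config, base_config, pretrained)
          vals <- cell_metrics(imp, target, plan, metrics, assoc_full,
                               screen_full, top_prog_genes,
                               reference_gene_list, seed = cell_seed)
          data.frame(method = method, missing_rate = rate, replicate = rep_idx,
                     metric = names(vals), value = as.numeric(unlist(vals)),
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          errors[[length(errors) + 1L]] <<- list(method = method, rate = rate,
                                                 replicate = rep_idx,
                                                 message = conditionMessage(e))
          NULL
        })
        if (!is.null(res)) cells[[length(cells) + 1L]] <- res
      }
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(method = character(), missing_rate = numeric(),
               replicate = integer(), metric = character(), value = numeric())
  summary <- stats::aggregate(value ~ method + missing_rate + metric, data = cells,
                              FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- cbind(summary[, c("method", "missing_rate", "metric")],
                   mean = summary$value[, "mean"], sd = summary$value[, "sd"])
  summary <- summary[order(summary$metric, summary$missing_rate, summary$method), ]
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary, errors = errors,
                 methods = methods, missing_rates = missing_rates,
                 n_replicates = n_replicates, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d methods x %d rates x %d replicates, %d metric cells, %d errors\n",
              length(x$methods), length(x$missing_rates), x$n_replicates,
              nrow(x$cells), length(x$errors)))
  invisible(x)
}

#' Write an evaluation report as tidy delimited tables
#'
#' `cells.tsv` holds one row per method x rate x replicate x metric;
#' `summary.tsv` the replicate mean and sd.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$cells, file.path(dir, "cells.tsv"), sep = "\t")
  data.table::fwrite(report$summary, file.path(dir, "summary.tsv"), sep = "\t")
  invisible(dir)
}
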