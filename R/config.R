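default_run_config <- function() {
  list(
    mode = "simulate",
    synthetic = unclass(synthetic_config()),
    cohort_dirs = NULL,
    target_cohort = NULL,
    methods = all_benchmark_methods(),
    metrics = all_benchmark_metrics(),
    missing_rates = c(0.1, 0.3, 0.5, 0.7, 0.9),
    n_replicates = 5L,
    seed = 1L,
    network = list(hidden_dim = 4000L, learning_rate = 1e-4,
                   pretrain_epochs = 300L, finetune_epochs = 150L,
                   pretrain_batch = 128L, finetune_batch = 16L),
    baselines = list(svd_rank = NULL, svd_tol = 1e-4, svd_max_iter = 100L,
                     tobmi_k = "auto", lasso_lambda = "cv"),
    reference_gene_list = NULL,
    output_dir = "panimpute_run"
  )
}

#' Validate and resolve a run configuration file
#'
#' Reads a YAML configuration, fills every unset field with the package
#' defaults (the tuned network hyper-parameters, the five standard missing
#' rates, five replicates) and validates types, ranges and referenced paths.
#' Any invalid field produces a human-readable error naming it.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return object of class `"run_config"` (a fully resolved named list).
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    stop("`path` must be a file path or a named list", call. = FALSE)
  }
  cfg <- utils::modifyList(default_run_config(), user, keep.null = TRUE)
  if (!cfg$mode %in% c("simulate", "load")) {
    stop("field `mode` must be \"simulate\" or \"load\"", call. = FALSE)
  }
  if (cfg$mode == "load") {
    if (is.null(cfg$cohort_dirs)) {
      stop("field `cohort_dirs` is required in load mode", call. = FALSE)
    }
    missing_dirs <- cfg$cohort_dirs[!dir.exists(unlist(cfg$cohort_dirs))]
    if (length(missing_dirs)) {
      stop("field `cohort_dirs`: nonexistent path(s) ",
           paste(missing_dirs, collapse = ", "), call. = FALSE)
    }
  } else {
    cfg$synthetic <- do.call(synthetic_config,
                             utils::modifyList(unclass(synthetic_config()),
                                               cfg$synthetic %||% list()))
  }
  if (any(cfg$missing_rates <= 0 | cfg$missing_rates >= 1)) {
    stop("field `missing_rates` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!all(cfg$methods %in% all_benchmark_methods())) {
    stop("field `methods`: unknown method(s) ",
         paste(setdiff(cfg$methods, all_benchmark_methods()), collapse = ", "),
         call. = FALSE)
  }
  if (!all(cfg$metrics %in% all_benchmark_metrics())) {
    stop("field `metrics`: unknown metric(s) ",
         paste(setdiff(cfg$metrics, all_benchmark_metrics()), collapse = ", "),
         call. = FALSE)
  }
  if (cfg$n_replicates < 1) stop("field `n_replicates` must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(cfg$seed, "seed")
  if (cfg$network$learning_rate <= 0) {
    stop("field `network.learning_rate` must be > 0", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Serialize a resolved run configuration to YAML
#'
#' A re-read of the written file resolves to an identical configuration, so
#' every run directory carries the exact configuration that produced it.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Execute the full simulate/impute/evaluate experiment
#'
#' Runs the pipeline described by a resolved configuration: generate (or
#' load) the cohorts, run every requested imputation method on every
#' missing-rate x replicate partition of the target cohort, compute the
#' requested metrics, and write all outputs under `output_dir`:
#' `resolved_config.yaml`, `cells.tsv`, `summary.tsv`, `log.txt`, plus
#' `cohorts/` and `ground_truth/` when simulating. Rerunning with the same
#' configuration reproduces the metric tables exactly.
#'
#' @param config a `run_config` from [validate_config()].
#' @return the output directory path, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "resolved_config.yaml"))
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)
  log_line("seed: %d", config$seed)

  if (config$mode == "simulate") {
    gen <- generate_multi_cohort(config$synthetic)
    cohorts <- gen$cohorts
    for (co in cohorts) write_cohort(co, file.path(out_dir, "cohorts", co$cohort_id))
    write_ground_truth(gen$truth, file.path(out_dir, "ground_truth"))
    log_line("simulated %d cohorts (%d samples each)", length(cohorts),
             config$synthetic$samples_per_cohort)
  } else {
    cohorts <- suppressMessages(lapply(unlist(config$cohort_dirs), read_cohort))
    log_line("loaded %d cohorts", length(cohorts))
  }
  cohort_ids <- vapply(cohorts, function(co) co$cohort_id, character(1))
  target_id <- config$target_cohort %||% cohort_ids[1L]
  if (!target_id %in% cohort_ids) {
    stop("field `target_cohort`: unknown cohort ", target_id, call. = FALSE)
  }
  n_cpg <- ncol(cohorts[[1L]]$methylation)
  n_gene <- ncol(cohorts[[1L]]$expression)
  net <- network_config(input_dim = n_cpg, output_dim = n_gene,
                        hidden_dim = config$network$hidden_dim,
                        learning_rate = config$network$learning_rate,
                        pretrain_epochs = config$network$pretrain_epochs,
                        finetune_epochs = config$network$finetune_epochs,
                        pretrain_batch = config$network$pretrain_batch,
                        finetune_batch = config$network$finetune_batch,
                        seed = config$seed)
  base <- baseline_config(svd_rank = config$baselines$svd_rank,
                          svd_tol = config$baselines$svd_tol,
                          svd_max_iter = config$baselines$svd_max_iter,
                          tobmi_k = config$baselines$tobmi_k,
                          lasso_lambda = config$baselines$lasso_lambda,
                          seed = config$seed)
  report <- benchmark_run(cohorts, target_id,
                          methods = config$methods,
                          missing_rates = config$missing_rates,
                          n_replicates = config$n_replicates,
                          seed = config$seed,
                          reference_gene_list = unlist(config$reference_gene_list),
                          net_config = net,
                          base_config = base,
                          metrics = config$metrics)
  write_report(report, out_dir)
  for (e in report$errors) {
    log_line("ERROR cell method=%s rate=%.2f replicate=%d: %s",
             e$method, e$rate, e$replicate, e$message)
  }
  log_line("grid: %d methods x %d rates x %d replicates -> %d metric cells",
           length(config$methods), length(config$missing_rates),
           config$n_replicates, nrow(report$cells))
  invisible(out_dir)
}
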