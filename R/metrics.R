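#' Imputation accuracy: RMSE, MAE and per-sample squared correlation
#'
#' RMSE is computed per sample over genes, `sqrt(mean((y - y0)^2))`, then
#' averaged over samples; MAE analogously with absolute error. `sample_r2`
#' is the mean over samples of the squared Pearson correlation between each
#' sample's imputed and true gene vectors. All on the log2 scale. Samples
#' whose true (or imputed) vector has zero variance have undefined
#' correlation and are excluded from `sample_r2` with a warning.
#'
#' @param imputed,truth matrices with identical sample and gene ids.
#' @return list with `rmse`, `mae`, `sample_r2`.
#' @export
imputation_metrics <- function(imputed, truth) {
  if (!identical(dimnames(imputed), dimnames(truth))) {
    stop("imputed and truth matrices must share sample and gene ids", call. = FALSE)
  }
  err <- imputed - truth
  rmse_s <- sqrt(rowMeans(err^2))
  mae_s <- rowMeans(abs(err))
  sd_t <- apply(truth, 1L, stats::sd)
  sd_i <- apply(imputed, 1L, stats::sd)
  ok <- sd_t > 0 & sd_i > 0
  if (!all(ok)) {
    warning(sprintf("%d samples with zero-variance vectors excluded from sample_r2", sum(!ok)))
  }
  r2_s <- rep(NA_real_, nrow(truth))
  for (i in which(ok)) r2_s[i] <- stats::cor(imputed[i, ], truth[i, ])^2
  list(rmse = mean(rmse_s), mae = mean(mae_s),
       sample_r2 = if (any(ok)) mean(r2_s[ok]) else NA_real_)
}

# two-sided p-value for a Pearson correlation, t-test with n-2 df
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                            lower.tail = FALSE))
  p
}

#' Strongest CpG-gene association per gene
#'
#' For every gene, the squared Pearson correlation against every CpG site is
#' computed and only the strongest CpG is kept. P-values come from the
#' two-sided correlation t-test with n - 2 degrees of freedom; q-values from
#' Benjamini-Hochberg across genes. A constant gene or CpG contributes a
#' correlation of 0 with p = 1. Argmax ties break by CpG id.
#'
#' @param meth,expr aligned sample-by-feature matrices, n >= 3 samples.
#' @return data.frame (class `"association_table"`) with one row per gene:
#'   `gene_id`, `cpg_id`, `r2`, `p`, `q`.
#' @export
cpg_gene_association <- function(meth, expr) {
  if (!identical(rownames(meth), rownames(expr))) {
    stop("methylation and expression samples are not aligned", call. = FALSE)
  }
  n <- nrow(meth)
  if (n < 3L) stop("association needs at least 3 samples", call. = FALSE)
  r <- suppressWarnings(stats::cor(meth, expr))   # CpG x gene
  r[is.na(r)] <- 0                                 # constant CpG or gene
  r2 <- r^2
  cpg_rank <- order(colnames(meth))
  cpg_pref <- match(seq_len(ncol(meth)), cpg_rank) # lower = earlier id
  best <- integer(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    m <- max(r2[, j])
    cand <- which(r2[, j] == m)
    best[j] <- cand[which.min(cpg_pref[cand])]
  }
  r_best <- r[cbind(best, seq_len(ncol(expr)))]
  p <- cor_pvalue(r_best, n)
  p[r_best == 0] <- 1
  out <- data.frame(gene_id = colnames(expr),
                    cpg_id = colnames(meth)[best],
                    r2 = r_best^2,
                    p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

# deterministic ranking of an association table: decreasing r2, ties by gene id
rank_pairs <- function(assoc) assoc[order(-assoc$r2, assoc$gene_id), , drop = FALSE]

#' Mean recovered correlation of the strongest CpG-gene pairs
#'
#' Takes the `top_k` CpG-gene pairs ranked by the full (unimputed) dataset's
#' R2 (ties by gene id), recomputes the squared correlation of those fixed
#' pairs on the imputed dataset, and returns the mean.
#'
#' @param assoc_full association table computed on the full dataset.
#' @param meth methylation matrix of the evaluation samples.
#' @param imputed_expr imputed expression over the same samples.
#' @param top_k number of pairs (default 100); if fewer genes exist, all are
#'   used with a warning.
#' @return mean recovered R2 of the fixed top pairs.
#' @export
top_pairs_mean_r2 <- function(assoc_full, meth, imputed_expr, top_k = 100) {
  if (!identical(rownames(meth), rownames(imputed_expr))) {
    stop("methylation and imputed expression samples are not aligned", call. = FALSE)
  }
  ranked <- rank_pairs(assoc_full)
  if (nrow(ranked) < top_k) {
    warning(sprintf("only %d genes available for top_k = %d", nrow(ranked), top_k))
    top_k <- nrow(ranked)
  }
  pairs <- ranked[seq_len(top_k), ]
  r2 <- mapply(function(cpg, gene) {
    x <- meth[, cpg]; y <- imputed_expr[, gene]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  }, pairs$cpg_id, pairs$gene_id)
  mean(r2)
}

#' Average precision (step-wise PR-AUC)
#'
#' Examples are ranked by decreasing score (ties broken by index order);
#' average precision sums precision at each positive's rank, divided by the
#' number of positives. No trapezoidal interpolation.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores, higher = more confident positive.
#' @return average precision in \[0, 1\].
#' @export
average_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (sum(labels) == 0) stop("average precision undefined with zero positive labels", call. = FALSE)
  ord <- order(-scores)
  lab <- labels[ord]
  cum_pos <- cumsum(lab)
  prec <- cum_pos / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab)
}

#' Recovery of methylation-driving genes from imputed data
#'
#' Driving genes are defined on the full data as genes whose strongest
#' CpG-gene pair has `r2 >= r2_min` and BH `q <= q_max`. Scores are the
#' imputed data's best-pair R2 per gene. Returns the average precision of
#' recovering the full-data labels from imputed scores, and the overlap of
#' the top-`top_k` gene lists (ranked by R2, ties by gene id).
#'
#' @param assoc_full,assoc_imputed association tables on the same gene
#'   universe.
#' @param r2_min,q_max driving-gene thresholds (defaults 0.5 and 0.05).
#' @param top_k list length for the overlap (default 100).
#' @return list with `prauc` and `overlap`.
#' @export
driving_gene_recovery <- function(assoc_full, assoc_imputed,
                                  r2_min = 0.5, q_max = 0.05, top_k = 100) {
  if (!setequal(assoc_full$gene_id, assoc_imputed$gene_id)) {
    stop("association tables cover different gene universes", call. = FALSE)
  }
  assoc_imputed <- assoc_imputed[match(assoc_full$gene_id, assoc_imputed$gene_id), ]
  labels <- as.integer(assoc_full$r2 >= r2_min & assoc_full$q <= q_max)
  if (sum(labels) == 0) stop("no driving genes in the full data; PR-AUC undefined", call. = FALSE)
  k <- min(top_k, nrow(assoc_full))
  top_full <- rank_pairs(assoc_full)$gene_id[seq_len(k)]
  top_imp <- rank_pairs(assoc_imputed)$gene_id[seq_len(k)]
  list(prauc = average_precision(labels, assoc_imputed$r2),
       overlap = length(intersect(top_full, top_imp)))
}

#' Enrichment factor of a selected gene list against a reference list
#'
#' `EF = (N_true / N_selected) / (N_active / N_total)`: the hit fraction
#' among the selected genes relative to the reference list's prevalence in
#' the whole universe. 1 is the random expectation.
#'
#' @param selected character vector of selected gene ids.
#' @param reference_list character vector of reference (active) gene ids.
#' @param n_total size of the gene universe.
#' @return the enrichment factor.
#' @export
enrichment_factor <- function(selected, reference_list, n_total) {
  if (length(reference_list) == 0) stop("empty reference list; EF undefined", call. = FALSE)
  n_true <- length(intersect(selected, reference_list))
  (n_true / length(selected)) / (length(reference_list) / n_total)
}

#' Recovery of prognosis-related genes from imputed data
#'
#' Labels are the full-data significance flags; scores are `-log10(p)` from
#' the imputed-data screen. Top-k lists are ranked by ascending p (ties by
#' gene id). The enrichment factor compares the imputed top-k list with an
#' external reference gene list.
#'
#' @param screen_full,screen_imputed outputs of [prognosis_gene_screen()]
#'   over the same gene universe.
#' @param reference_list external prognosis-related gene ids.
#' @param n_total gene-universe size (defaults to the screen's gene count).
#' @param top_k list length (default 100).
#' @return list with `prauc`, `overlap`, `enrichment_factor`.
#' @export
prognosis_gene_recovery <- function(screen_full, screen_imputed, reference_list,
                                    n_total = nrow(screen_full), top_k = 100) {
  if (!setequal(screen_full$gene_id, screen_imputed$gene_id)) {
    stop("screens cover different gene universes", call. = FALSE)
  }
  screen_imputed <- screen_imputed[match(screen_full$gene_id, screen_imputed$gene_id), ]
  labels <- as.integer(screen_full$flag)
  if (sum(labels) == 0) stop("no prognosis-related genes in the full data", call. = FALSE)
  k <- min(top_k, nrow(screen_full))
  rank_p <- function(s) s$gene_id[order(s$p, s$gene_id)][seq_len(k)]
  top_imp <- rank_p(screen_imputed)
  list(prauc = average_precision(labels, -log10(pmax(screen_imputed$p, 1e-300))),
       overlap = length(intersect(rank_p(screen_full), top_imp)),
       enrichment_factor = enrichment_factor(top_imp, reference_list, n_total))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' from the contingency-table formula; symmetric and label-permutation
#' invariant, bounded above by 1.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Clustering concordance between imputed and actual expression
#'
#' K-means (10 restarts, seeded) partitions the samples of each dataset,
#' restricted to `gene_subset` (typically the top-100 prognosis-ranked
#' genes), into `k` clusters; agreement is the adjusted Rand index. A
#' degenerate K-means run (empty cluster) is retried with a shifted seed, at
#' most 5 times.
#'
#' @param expr_imputed,expr_full expression matrices over the same samples.
#' @param gene_subset gene ids to cluster on.
#' @param k number of clusters (default 2).
#' @param seed RNG seed.
#' @return list with `ari`, `labels_imputed`, `labels_full`.
#' @export
cluster_concordance <- function(expr_imputed, expr_full, gene_subset, k = 2, seed = 1L) {
  if (!identical(rownames(expr_imputed), rownames(expr_full))) {
    stop("imputed and full expression samples are not aligned", call. = FALSE)
  }
  if (nrow(expr_full) < k) stop("fewer samples than clusters", call. = FALSE)
  run_kmeans <- function(x, seed) {
    for (attempt in 0:4) {
      res <- try(with_rng_seed(seed + attempt,
                               stats::kmeans(x, centers = k, nstart = 10)),
                 silent = TRUE)
      if (!inherits(res, "try-error")) return(res$cluster)
    }
    stop("K-means failed after 5 seed attempts", call. = FALSE)
  }
  li <- run_kmeans(expr_imputed[, gene_subset, drop = FALSE], seed)
  lf <- run_kmeans(expr_full[, gene_subset, drop = FALSE], seed)
  list(ari = adjusted_rand_index(li, lf), labels_imputed = li, labels_full = lf)
}

#' Harrell concordance index
#'
#' Over comparable pairs (the earlier time is an observed event), the
#' fraction in which the earlier-failing sample has the higher predicted
#' risk; risk ties score 0.5.
#'
#' @param risk predicted risk scores (higher = worse prognosis).
#' @param time follow-up times.
#' @param event event indicators (1 = death).
#' @return the C-index.
#' @export
harrell_cindex <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; total <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comp <- which(time > time[i])
    if (!length(comp)) next
    total <- total + length(comp)
    conc <- conc + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (total == 0) return(NA_real_)
  conc / total
}
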