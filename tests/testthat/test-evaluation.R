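test_that("imputation accuracy metrics match hand arithmetic", {
  mk <- function(v, ids) matrix(v, length(ids), length(v) / length(ids), byrow = TRUE,
                                dimnames = list(ids, paste0("g", seq_len(length(v) / length(ids)))))
  # one sample, two genes, errors (+1, -1): rmse 1, mae 1
  truth <- matrix(c(3, 5), 1, 2, dimnames = list("s1", c("g1", "g2")))
  imp <- truth + c(1, -1)
  m <- suppressWarnings(imputation_metrics(imp, truth))
  expect_equal(m$rmse, 1)
  expect_equal(m$mae, 1)
  # reported rmse is the mean of per-sample values: samples with rmse 1 and 3
  truth2 <- rbind(s1 = c(0, 0), s2 = c(0, 0)); colnames(truth2) <- c("g1", "g2")
  imp2 <- rbind(s1 = c(1, -1), s2 = c(3, -3)); colnames(imp2) <- c("g1", "g2")
  expect_equal(suppressWarnings(imputation_metrics(imp2, truth2))$rmse, 2)
  # perfect imputation
  x <- tiny_matrix(4, 6, prefix = "g")
  p <- imputation_metrics(x, x)
  expect_equal(p$rmse, 0); expect_equal(p$mae, 0); expect_equal(p$sample_r2, 1)
  # zero-variance truth sample excluded with a warning
  truth3 <- rbind(s1 = c(2, 2, 2), s2 = c(1, 2, 3))
  colnames(truth3) <- paste0("g", 1:3)
  imp3 <- truth3 + 0.1
  expect_warning(m3 <- imputation_metrics(imp3, truth3), "zero-variance")
  expect_equal(m3$sample_r2, 1)
})

test_that("metrics are invariant to consistent sample reordering", {
  x <- tiny_matrix(6, 8, seed = 4, prefix = "g")
  y <- x + matrix(rnorm(48, 0, 0.2), 6, 8)
  dimnames(y) <- dimnames(x)
  m1 <- imputation_metrics(y, x)
  ord <- c(4, 2, 6, 1, 3, 5)
  m2 <- imputation_metrics(y[ord, ], x[ord, ])
  expect_equal(m1, m2)
})

test_that("per-gene association picks the strongest CpG with correct p and q", {
  # gene identical to one CpG -> that CpG selected with R2 = 1
  meth <- omics_matrix(cbind(cg1 = c(0.1, 0.2, 0.3, 0.4), cg2 = c(0.4, 0.1, 0.3, 0.2)),
                       sample_ids = paste0("s", 1:4))
  expr <- omics_matrix(cbind(g1 = c(0.1, 0.2, 0.3, 0.4) * 10), sample_ids = paste0("s", 1:4))
  tab <- cpg_gene_association(meth, expr)
  expect_equal(tab$cpg_id, "cg1")
  expect_equal(tab$r2, 1)
  expect_equal(tab$p, 0)
  # hand Pearson values on 4 points
  meth2 <- omics_matrix(cbind(cg1 = c(1, 2, 3, 4) / 10), sample_ids = paste0("s", 1:4))
  e1 <- omics_matrix(cbind(g1 = c(2, 4, 6, 8)), sample_ids = paste0("s", 1:4))
  e2 <- omics_matrix(cbind(g1 = c(1, 3, 2, 4)), sample_ids = paste0("s", 1:4))
  expect_equal(cpg_gene_association(meth2, e1)$r2, 1)
  expect_equal(cpg_gene_association(meth2, e2)$r2, 0.64)
  # p-value agrees with cor.test
  ct <- cor.test(c(1, 3, 2, 4), 1:4)
  expect_equal(cpg_gene_association(meth2, e2)$p, unname(ct$p.value))
  # constant gene: correlation treated as 0 with p = 1
  e3 <- omics_matrix(cbind(g1 = rep(5, 4)), sample_ids = paste0("s", 1:4))
  t3 <- cpg_gene_association(meth2, e3)
  expect_equal(t3$r2, 0); expect_equal(t3$p, 1)
})

test_that("BH q-values follow the step-up procedure", {
  meth <- tiny_matrix(10, 3, seed = 6, prefix = "cg")
  expr <- tiny_matrix(10, 4, seed = 7, prefix = "g")
  tab <- cpg_gene_association(meth, expr)
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
  # the documented hand case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_true(all(tab$q >= tab$p))
})

test_that("top-pair mean R2 behaves at its fixed points", {
  gen <- small_cohorts(seed = 31, n_cohorts = 2)
  co <- gen$cohorts[[1]]
  assoc <- cpg_gene_association(co$methylation, co$expression)
  # imputed = full data reproduces the full-data top-k mean
  ranked <- assoc[order(-assoc$r2, assoc$gene_id), ]
  expect_equal(top_pairs_mean_r2(assoc, co$methylation, co$expression, top_k = 10),
               mean(ranked$r2[1:10]))
  # top_k = 1 equals the single best pair
  expect_equal(top_pairs_mean_r2(assoc, co$methylation, co$expression, top_k = 1),
               ranked$r2[1])
  # expression replaced by independent noise: tiny recovered correlation
  noise <- co$expression
  noise[] <- withr::with_seed(1, rnorm(length(noise)))
  expect_lt(top_pairs_mean_r2(assoc, co$methylation, noise, top_k = 10), 0.2)
  # more pairs requested than genes: warns and uses all
  expect_warning(v <- top_pairs_mean_r2(assoc, co$methylation, co$expression,
                                        top_k = 1000), "top_k")
  expect_equal(v, mean(assoc$r2))
})

test_that("average precision matches step-wise enumeration", {
  expect_equal(average_precision(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)),
               (1 / 1 + 2 / 3) / 2)
  # all positives ranked first -> 1
  expect_equal(average_precision(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_error(average_precision(c(0, 0), c(1, 2)), "zero positive")
  # random scores converge to prevalence in expectation
  withr::local_seed(5)
  ap <- replicate(100, average_precision(rep(c(1, 0), c(200, 800)), runif(1000)))
  expect_equal(mean(ap), 0.2, tolerance = 0.03)
})

test_that("driving-gene recovery scores labels from full data with imputed scores", {
  gen <- small_cohorts(seed = 33, n_cohorts = 2, n = 80, n_driving = 10)
  co <- gen$cohorts[[1]]
  assoc <- cpg_gene_association(co$methylation, co$expression)
  # self-recovery: perfect PR-AUC and full top-k overlap
  rec <- driving_gene_recovery(assoc, assoc, top_k = 10)
  expect_equal(rec$prauc, 1)
  expect_equal(rec$overlap, 10)
  # degraded scores reduce both
  shuffled <- assoc
  shuffled$r2 <- withr::with_seed(2, sample(shuffled$r2))
  rec2 <- driving_gene_recovery(assoc, shuffled, top_k = 10)
  expect_lt(rec2$prauc, 1)
  expect_error(driving_gene_recovery(assoc, assoc, r2_min = 2), "no driving genes")
})

test_that("enrichment factor follows its defining ratio", {
  # N_true 10 of 100 selected vs 1000 active in 20000 -> 2.0
  universe <- sprintf("g%05d", 1:20000)
  reference <- universe[1:1000]
  selected <- c(universe[1:10], universe[2000:2089])
  expect_equal(enrichment_factor(selected, reference, 20000), 2.0)
  # selecting the whole universe gives 1
  expect_equal(enrichment_factor(universe, reference, 20000), 1)
  # no selected gene in the reference gives 0
  expect_equal(enrichment_factor(universe[1500:1599], reference, 20000), 0)
  expect_error(enrichment_factor(selected, character(0), 20000), "empty reference")
})

test_that("adjusted Rand index matches the contingency-table formula", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # label-permutation invariance
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # the classic crossed case
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  # symmetry and independent-oracle agreement
  withr::local_seed(8)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  expect_lte(adjusted_rand_index(a, b), 1)
})

test_that("clustering concordance is 1 on identical data and seeded", {
  gen <- small_cohorts(seed = 35, n_cohorts = 2, n = 30)
  co <- gen$cohorts[[1]]
  genes <- colnames(co$expression)[1:10]
  cc <- cluster_concordance(co$expression, co$expression, genes, k = 2, seed = 4)
  expect_equal(cc$ari, 1)
  cc2 <- cluster_concordance(co$expression, co$expression, genes, k = 2, seed = 4)
  expect_identical(cc$labels_imputed, cc2$labels_imputed)
})

test_that("Harrell C-index matches pair enumeration and survival::concordance", {
  # 4 uncensored records, one discordant pair of 6
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  risk <- c(4, 3, 1, 2)   # discordant only for the (3,4) pair
  expect_equal(harrell_cindex(risk, time, event), 5 / 6)
  # perfect ordering
  expect_equal(harrell_cindex(c(9, 7, 5, 3), time, event), 1)
  # risk ties score 0.5
  expect_equal(harrell_cindex(c(1, 1, 1, 1), time, event), 0.5)
  # censored records only count as later-time comparators
  surv <- toy_survival()
  risk2 <- c(6, 5, 4, 3, 2, 1)
  conc <- survival::concordance(survival::Surv(surv$time, surv$event) ~ risk2,
                                reverse = TRUE)
  expect_equal(harrell_cindex(risk2, surv$time, surv$event),
               unname(conc$concordance))
})

test_that("univariate Cox screening matches a partial-likelihood grid oracle", {
  surv <- toy_survival()
  x <- c(0.9, 0.2, 0.5, 0.8, 0.1, 0.4)   # not perfectly concordant with time
  expr <- matrix(x, 6, 1, dimnames = list(surv$sample_id, "g1"))
  screen <- prognosis_gene_screen(expr, surv)
  # dense grid search over the Breslow partial log-likelihood
  events <- which(surv$event == 1)
  pll <- function(b) {
    sum(vapply(events, function(i) {
      at_risk <- surv$time >= surv$time[i]
      b * x[i] - log(sum(exp(b * x[at_risk])))
    }, numeric(1)))
  }
  grid <- seq(-20, 20, by = 1e-3)
  b_hat <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_equal(screen$coef, b_hat, tolerance = 1e-3)
  # coxph cross-check
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x, ties = "breslow")
  expect_equal(screen$coef, unname(coef(fit)), tolerance = 1e-8)
  # constant gene degenerates cleanly
  expr0 <- cbind(expr, g2 = 0)
  s0 <- prognosis_gene_screen(expr0, surv)
  expect_equal(s0$coef[2], 0); expect_equal(s0$p[2], 1); expect_false(s0$flag[2])
})

test_that("prognosis-gene recovery combines PR-AUC, overlap and enrichment", {
  screen <- data.frame(gene_id = paste0("g", 1:6),
                       coef = rnorm(6),
                       p = c(0.01, 0.2, 0.03, 0.5, 0.04, 0.9),
                       flag = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  rec <- prognosis_gene_recovery(screen, screen, reference_list = c("g1", "g3"),
                                 top_k = 3)
  expect_equal(rec$prauc, 1)
  expect_equal(rec$overlap, 3)
  # top-3 by p = {g1,g3,g5}; 2 hits; EF = (2/3)/(2/6) = 2
  expect_equal(rec$enrichment_factor, 2)
})

test_that("KM/log-rank matches a hand-enumerated risk-set computation", {
  # 6 subjects, two groups
  surv <- survival_records(paste0("s", 1:6),
                           time = c(2, 4, 6, 3, 5, 7),
                           event = c(1, 1, 1, 1, 1, 0))
  g <- c("A", "A", "A", "B", "B", "B")
  res <- km_logrank(surv, g)
  # hand risk-set enumeration (observed - expected under the null, group A)
  # event times: 2,3,4,5,6 with risk sets {6,5,4,3,2} and A at risk {3,2,2,1,1}
  oA <- c(1, 0, 1, 0, 1)
  eA <- c(3 / 6, 2 / 5, 2 / 4, 1 / 3, 1 / 2)
  vA <- eA * (1 - eA)  # all d=1, no ties
  chi2 <- sum(oA - eA)^2 / sum(vA)
  expect_equal(res$chi2, chi2, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2, 1, lower.tail = FALSE))
  # identical event patterns across groups: chi2 ~ 0, p ~ 1
  surv2 <- survival_records(paste0("s", 1:6),
                            time = c(1, 2, 3, 1, 2, 3),
                            event = c(1, 1, 0, 1, 1, 0))
  res2 <- km_logrank(surv2, g)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-9)
  # no censoring: KM equals the empirical survival fraction at event times
  surv3 <- survival_records(paste0("s", 1:4), c(1, 2, 3, 4), rep(1, 4))
  res3 <- km_logrank(surv3, c("A", "A", "B", "B"))
  kmA <- res3$km_curves[res3$km_curves$group == "A", ]
  expect_equal(kmA$surv, c(0.5, 0))
  # a group with zero events: warned, p = 1
  surv4 <- survival_records(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_warning(res4 <- km_logrank(surv4, c("A", "A", "B", "B")), "zero events")
  expect_equal(res4$p, 1)
})

test_that("ridge Cox survival evaluation produces sane C-indices", {
  gen <- small_cohorts(seed = 37, n_cohorts = 2, n = 60, n_gene = 20, n_prog = 5)
  co <- gen$cohorts[[1]]
  screen <- prognosis_gene_screen(co$expression, co$survival)
  sig <- screen$gene_id[screen$flag]
  expect_gt(length(sig), 1)
  res <- survival_model_eval(co$expression, co$survival, sig, seed = 2)
  expect_gt(res$cindex, 0.5)
  expect_lte(res$cindex, 1)
  # no significant genes: 0.5 with flag
  res0 <- survival_model_eval(co$expression, co$survival, character(0))
  expect_equal(res0$cindex, 0.5)
  expect_true(attr(res0, "no_genes"))
})
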