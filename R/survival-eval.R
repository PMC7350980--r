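#' Univariate Cox screening of genes against overall survival
#'
#' One single-covariate Cox proportional-hazards fit per gene (Breslow tie
#' handling, Wald p-value); genes with `p <= p_max` are flagged as
#' prognosis-related. A constant gene gets coefficient 0 and p = 1; a
#' non-converging fit is flagged `FALSE` with its p set to 1 and the gene
#' recorded in attribute `"failed"` rather than crashing the screen.
#'
#' @param expr expression matrix, samples in rows.
#' @param survival data.frame from [survival_records()] covering the same
#'   samples (matched by `sample_id`).
#' @param p_max significance threshold (default 0.05).
#' @return data.frame with `gene_id`, `coef`, `p`, `flag`.
#' @export
prognosis_gene_screen <- function(expr, survival, p_max = 0.05) {
  surv <- survival[match(rownames(expr), survival$sample_id), ]
  if (anyNA(surv$sample_id)) stop("survival records missing for some samples", call. = FALSE)
  if (sum(surv$event) < 2) stop("screen needs at least 2 events", call. = FALSE)
  y <- survival::Surv(surv$time, surv$event)
  genes <- colnames(expr)
  coefs <- numeric(length(genes))
  pvals <- rep(1, length(genes))
  failed <- character(0)
  for (j in seq_along(genes)) {
    x <- expr[, j]
    if (stats::sd(x) == 0) next                     # constant gene: coef 0, p 1
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      failed <- c(failed, genes[j])
      next
    }
    b <- stats::coef(fit)[[1L]]
    se <- sqrt(stats::vcov(fit)[1L, 1L])
    coefs[j] <- b
    pvals[j] <- if (is.finite(se) && se > 0) {
      2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
    } else 1
  }
  out <- data.frame(gene_id = genes, coef = coefs, p = pvals,
                    flag = pvals <= p_max, stringsAsFactors = FALSE)
  attr(out, "failed") <- failed
  out
}

#' Ridge-penalized Cox survival prediction, scored by Harrell's C-index
#'
#' Fits an L2-penalized Cox model on the significant genes (those flagged in
#' the imputed-data screen); the penalty is chosen by 5-fold cross-validated
#' partial likelihood when `penalty = "cv"`, otherwise fixed. The C-index of
#' the fitted linear risk scores against the observed times is returned.
#' With no significant genes the C-index is reported as 0.5 with attribute
#' `"no_genes" = TRUE`.
#'
#' @param expr_imputed expression matrix, samples in rows.
#' @param survival data.frame from [survival_records()].
#' @param significant_genes character vector of gene ids to include.
#' @param penalty `"cv"` or a fixed nonnegative lambda.
#' @param seed seed for the cross-validation folds.
#' @return list with `cindex` (and attribute flag when degenerate).
#' @export
survival_model_eval <- function(expr_imputed, survival, significant_genes,
                                penalty = "cv", seed = 1L) {
  surv <- survival[match(rownames(expr_imputed), survival$sample_id), ]
  if (sum(surv$event) < 2) stop("survival model needs at least 2 events", call. = FALSE)
  significant_genes <- intersect(significant_genes, colnames(expr_imputed))
  if (length(significant_genes) == 0) {
    out <- list(cindex = 0.5)
    attr(out, "no_genes") <- TRUE
    return(out)
  }
  X <- expr_imputed[, significant_genes, drop = FALSE]
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    out <- list(cindex = 0.5)
    attr(out, "no_genes") <- TRUE
    return(out)
  }
  y <- survival::Surv(surv$time, surv$event)
  risk <- NULL
  if (ncol(X) >= 2) {
    risk <- tryCatch({
      if (identical(penalty, "cv")) {
        foldid <- with_rng_seed(seed, sample(rep_len(seq_len(5L), nrow(X))))
        cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 0, foldid = foldid)
        as.vector(stats::predict(cv, newx = X, s = "lambda.min", type = "link"))
      } else {
        fit <- glmnet::glmnet(X, y, family = "cox", alpha = 0)
        as.vector(stats::predict(fit, newx = X, s = penalty, type = "link"))
      }
    }, error = function(e) NULL)
  }
  if (is.null(risk)) {
    # single gene, or a degenerate penalized fit: unpenalized Cox
    fit <- tryCatch(survival::coxph(y ~ X, ties = "breslow"), error = function(e) NULL)
    if (is.null(fit)) {
      out <- list(cindex = 0.5)
      attr(out, "fit_failed") <- TRUE
      return(out)
    }
    risk <- as.vector(X %*% stats::coef(fit))
  }
  list(cindex = harrell_cindex(risk, surv$time, surv$event))
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group and the two-sample log-rank
#' chi-square (1 df) with its p-value. A group with zero events yields p = 1
#' with a warning.
#'
#' @param survival data.frame from [survival_records()].
#' @param group_labels vector of two group labels, one per record.
#' @return list with `km_curves` (data.frame: group, time, surv),
#'   `chi2`, `p`.
#' @export
km_logrank <- function(survival, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  events_per_group <- tapply(survival$event, g, sum)
  y <- survival::Surv(survival$time, survival$event)
  sf <- survival::survfit(y ~ g)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^g=", "", strata), time = sf$time, surv = sf$surv,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   stringsAsFactors = FALSE)
  if (any(events_per_group == 0)) {
    warning("a group has zero events; log-rank p set to 1")
    return(list(km_curves = km, chi2 = 0, p = 1))
  }
  sd_fit <- survival::survdiff(y ~ g)
  chi2 <- sd_fit$chisq
  list(km_curves = km, chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
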