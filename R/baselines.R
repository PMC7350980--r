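#' Configuration for the baseline imputers
#'
#' @param svd_rank truncation rank for iterative SVD completion; `NULL` picks
#'   `min(10, min(dim) - 1)` at run time.
#' @param svd_tol convergence threshold on the maximum relative change of
#'   imputed cells (default 1e-4).
#' @param svd_max_iter iteration cap (default 100).
#' @param tobmi_k donor count for kNN-weighted imputation, or `"auto"` for
#'   `ceiling(sqrt(n_train))`.
#' @param lasso_lambda per-gene L1 penalty: `"cv"` for 5-fold
#'   cross-validation, or a fixed nonnegative value.
#' @param seed seed for cross-validation folds.
#' @return object of class `"baseline_config"`.
#' @export
baseline_config <- function(svd_rank = NULL, svd_tol = 1e-4, svd_max_iter = 100,
                            tobmi_k = "auto", lasso_lambda = "cv", seed = 1L) {
  if (!is.null(svd_rank) && svd_rank < 1) stop("`svd_rank` must be >= 1", call. = FALSE)
  if (svd_tol <= 0) stop("`svd_tol` must be > 0", call. = FALSE)
  if (!identical(tobmi_k, "auto") && tobmi_k < 1) stop("`tobmi_k` must be >= 1", call. = FALSE)
  structure(list(svd_rank = svd_rank, svd_tol = svd_tol,
                 svd_max_iter = as.integer(svd_max_iter),
                 tobmi_k = tobmi_k, lasso_lambda = lasso_lambda,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Per-gene mean imputation
#'
#' Every test sample receives the per-gene mean of the training expression.
#'
#' @param train_expr training expression matrix, samples in rows.
#' @param test_sample_ids ids of the samples to impute.
#' @return imputed expression matrix, one identical row per test sample.
#' @export
mean_impute <- function(train_expr, test_sample_ids) {
  validate_omics(train_expr)
  if (nrow(train_expr) < 1L) stop("empty training set", call. = FALSE)
  mu <- colMeans(train_expr)
  out <- matrix(mu, nrow = length(test_sample_ids), ncol = ncol(train_expr),
                byrow = TRUE, dimnames = list(test_sample_ids, colnames(train_expr)))
  out
}

#' Trans-omics kNN-weighted imputation
#'
#' For each test sample, the `k` training samples nearest in Euclidean
#' methylation distance donate expression, combined by inverse-distance
#' weights `w_i = (1/d_i) / sum_j (1/d_j)`. A zero-distance donor returns
#' that donor's expression exactly. Distance ties are broken by training
#' sample id order.
#'
#' @param train_meth,train_expr aligned training blocks.
#' @param test_meth methylation of the samples to impute (same CpG ids).
#' @param k donor count, or `"auto"` for `ceiling(sqrt(n_train))`.
#' @return imputed expression matrix for the test samples.
#' @export
tobmi_impute <- function(train_meth, train_expr, test_meth, k = "auto") {
  if (!identical(rownames(train_meth), rownames(train_expr))) {
    stop("training methylation and expression are not aligned", call. = FALSE)
  }
  if (!identical(colnames(train_meth), colnames(test_meth))) {
    stop("train and test CpG ids differ", call. = FALSE)
  }
  n_train <- nrow(train_meth)
  if (identical(k, "auto")) k <- ceiling(sqrt(n_train))
  if (k > n_train) stop(sprintf("k = %d exceeds the %d training samples", k, n_train),
                        call. = FALSE)
  train_order <- order(rownames(train_meth))
  out <- matrix(NA_real_, nrow(test_meth), ncol(train_expr),
                dimnames = list(rownames(test_meth), colnames(train_expr)))
  sq_train <- rowSums(train_meth^2)
  for (i in seq_len(nrow(test_meth))) {
    x <- test_meth[i, ]
    d2 <- pmax(sq_train - 2 * as.vector(train_meth %*% x) + sum(x^2), 0)
    d <- sqrt(d2)
    sel <- order(d, train_order)[seq_len(k)]
    if (any(d[sel] == 0)) {
      donor <- sel[which(d[sel] == 0)][1L]
      out[i, ] <- train_expr[donor, ]
    } else {
      w <- (1 / d[sel]) / sum(1 / d[sel])
      out[i, ] <- as.vector(w %*% train_expr[sel, , drop = FALSE])
    }
  }
  out
}

#' Iterative truncated-SVD imputation of a missing expression block
#'
#' Works on the concatenated `[methylation | expression]` matrix in which the
#' expression block is missing for the test samples. Missing cells start at
#' the per-gene training means; each iteration replaces them with the values
#' of the rank-`r` truncated SVD reconstruction, until the maximum relative
#' change of the imputed cells drops below `svd_tol` or `svd_max_iter` is
#' reached (a warning flag, attribute `"converged"`, records the outcome).
#' Attribute `"obs_error"` traces the Frobenius reconstruction error on the
#' observed cells across iterations.
#'
#' @param meth_all methylation for all samples (train + test).
#' @param expr_with_missing_block expression matrix over the same samples
#'   with `NA` rows for the test samples.
#' @param config a `baseline_config`.
#' @return imputed expression matrix for the originally missing samples.
#' @export
svd_impute <- function(meth_all, expr_with_missing_block, config = baseline_config()) {
  if (!identical(rownames(meth_all), rownames(expr_with_missing_block))) {
    stop("methylation and expression sample ids differ", call. = FALSE)
  }
  if (anyNA(meth_all)) stop("methylation block must be complete", call. = FALSE)
  expr <- expr_with_missing_block
  miss_row <- rowSums(is.na(expr)) > 0L
  if (!any(miss_row)) {
    attr(expr, "converged") <- TRUE
    attr(expr, "iterations") <- 0L
    return(expr)
  }
  if (!all(is.na(expr[miss_row, , drop = FALSE]))) {
    stop("expression must be missing for whole samples (block missingness)", call. = FALSE)
  }
  if (anyNA(expr[!miss_row, , drop = FALSE])) {
    stop("training expression rows must be complete", call. = FALSE)
  }
  X <- cbind(meth_all, expr)
  miss <- is.na(X)
  train_means <- colMeans(expr[!miss_row, , drop = FALSE])
  X[miss] <- matrix(train_means, sum(miss_row), ncol(expr), byrow = TRUE)
  r <- config$svd_rank %||% min(10L, min(dim(X)) - 1L)
  r <- min(r, min(dim(X)))
  converged <- FALSE
  obs_error <- numeric(0)
  iterations <- 0L
  for (iter in seq_len(config$svd_max_iter)) {
    sv <- svd(X, nu = r, nv = r)
    recon <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
    obs_error <- c(obs_error, sqrt(sum((recon[!miss] - X[!miss])^2)))
    old <- X[miss]
    X[miss] <- recon[miss]
    iterations <- iter
    delta <- max(abs(X[miss] - old) / pmax(abs(old), 1e-12))
    if (delta < config$svd_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("SVD imputation did not converge in %d iterations", config$svd_max_iter))
  }
  out <- X[miss_row, ncol(meth_all) + seq_len(ncol(expr)), drop = FALSE]
  dimnames(out) <- list(rownames(expr)[miss_row], colnames(expr))
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "obs_error") <- obs_error
  out
}

#' Per-gene lasso imputation of expression from methylation
#'
#' One L1-penalized linear regression per gene (coordinate descent via
#' glmnet, unpenalized intercept, unstandardized design so the penalty acts
#' on the stated coefficient scale), with the penalty chosen per gene by
#' 5-fold cross-validation (`lambda = "cv"`) or fixed. Fit on log2-scale
#' expression; the linear model needs no \[0, 1\] scaling.
#'
#' @param train_meth,train_expr aligned training blocks.
#' @param test_meth methylation of the samples to impute.
#' @param lambda `"cv"` or a fixed nonnegative penalty.
#' @param seed seed for the cross-validation folds.
#' @return imputed expression matrix for the test samples.
#' @export
lasso_impute <- function(train_meth, train_expr, test_meth, lambda = "cv", seed = 1L) {
  if (!identical(rownames(train_meth), rownames(train_expr))) {
    stop("training methylation and expression are not aligned", call. = FALSE)
  }
  if (!identical(colnames(train_meth), colnames(test_meth))) {
    stop("train and test CpG ids differ", call. = FALSE)
  }
  n <- nrow(train_meth)
  if (identical(lambda, "cv") && n < 5L) {
    stop("cross-validated lambda needs at least 5 training samples", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(test_meth), ncol(train_expr),
                dimnames = list(rownames(test_meth), colnames(train_expr)))
  foldid <- NULL
  if (identical(lambda, "cv")) {
    foldid <- with_rng_seed(seed, sample(rep_len(seq_len(5L), n)))
  }
  for (j in seq_len(ncol(train_expr))) {
    y <- train_expr[, j]
    if (stats::sd(y) == 0) {       # constant gene: lasso degenerates to its mean
      out[, j] <- y[1L]
      next
    }
    if (identical(lambda, "cv")) {
      fit <- glmnet::cv.glmnet(train_meth, y, alpha = 1, standardize = FALSE,
                               foldid = foldid)
      pred <- stats::predict(fit, newx = test_meth, s = "lambda.min")
    } else {
      # warm-start path ending exactly at the requested penalty
      lam_path <- sort(unique(c(lambda * 2^(6:1), lambda)), decreasing = TRUE)
      fit <- glmnet::glmnet(train_meth, y, alpha = 1, standardize = FALSE,
                            lambda = lam_path, thresh = 1e-10)
      pred <- stats::predict(fit, newx = test_meth, s = lambda)
    }
    if (any(!is.finite(pred))) {
      stop(sprintf("non-finite lasso prediction for gene %s", colnames(train_expr)[j]),
           call. = FALSE)
    }
    out[, j] <- as.vector(pred)
  }
  out
}
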