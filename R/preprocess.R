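#' Variance-stabilizing log transform of expression values
#'
#' Elementwise `log2(G + 1)` on raw (RSEM-style) expression values.
#'
#' @param expr nonnegative expression matrix, samples in rows.
#' @return transformed matrix, same ids.
#' @export
log2_transform <- function(expr) {
  validate_omics(expr)
  if (min(expr) < 0) stop("expression values must be nonnegative before log2(G+1)", call. = FALSE)
  log2(expr + 1)
}

#' Drop genes that are zero in every sample
#'
#' Applied to raw (pre-log) expression. Dropped gene ids are attached as
#' attribute `"dropped"` and counted in a message.
#'
#' @param expr expression matrix, samples in rows.
#' @return filtered matrix.
#' @export
filter_expression_genes <- function(expr) {
  validate_omics(expr)
  all_zero <- colSums(expr != 0) == 0L
  if (all(all_zero)) stop("all genes are zero across all samples", call. = FALSE)
  out <- expr[, !all_zero, drop = FALSE]
  if (any(all_zero)) {
    message(sprintf("dropped %d all-zero genes", sum(all_zero)))
  }
  attr(out, "dropped") <- colnames(expr)[all_zero]
  out
}

#' Filter CpG sites with missing values or low variance
#'
#' First removes sites containing any missing value, then removes sites whose
#' sample variance (n - 1 denominator) over all samples is below
#' `var_threshold`. Site order is preserved.
#'
#' @param meth methylation matrix, beta values in \[0, 1\] or `NA`.
#' @param var_threshold minimum variance, default 0.05.
#' @return filtered matrix; dropped ids in attribute `"dropped"`.
#' @export
filter_methylation_sites <- function(meth, var_threshold = 0.05) {
  validate_omics(meth, allow_na = TRUE)
  has_na <- colSums(is.na(meth)) > 0L
  kept <- meth[, !has_na, drop = FALSE]
  v <- apply(kept, 2L, stats::var)
  low <- v < var_threshold
  out <- kept[, !low, drop = FALSE]
  if (ncol(out) == 0L) stop("all methylation sites removed by NA/variance filtering", call. = FALSE)
  attr(out, "dropped") <- c(colnames(meth)[has_na], colnames(kept)[low])
  out
}

#' Quantile-normalize a cohort onto a reference distribution
#'
#' Maps each target sample's values, by rank, onto the empirical quantiles of
#' the pooled reference value distribution, so that the normalized cohort has
#' the same overall distribution as the reference. The mapping is monotone
#' within each sample.
#'
#' @param target matrix to normalize, samples in rows.
#' @param reference matrix defining the target distribution; must carry the
#'   same feature ids.
#' @return normalized target matrix.
#' @export
quantile_normalize_to_reference <- function(target, reference) {
  validate_omics(target)
  validate_omics(reference)
  if (!setequal(colnames(target), colnames(reference))) {
    stop("target and reference feature ids differ", call. = FALSE)
  }
  pool <- sort(as.vector(reference))
  p <- ncol(target)
  out <- target
  for (i in seq_len(nrow(target))) {
    r <- rank(target[i, ], ties.method = "average")
    probs <- if (p == 1L) 0.5 else (r - 1) / (p - 1)
    out[i, ] <- stats::quantile(pool, probs = probs, type = 7, names = FALSE)
  }
  out
}

#' Fit a per-feature min-max scaler
#'
#' The network's sigmoid output layer bounds predictions to (0, 1), so
#' expression targets are affinely mapped to \[0, 1\] per gene. The scaler is
#' fitted once on the pretraining corpus and frozen through fine-tuning.
#'
#' @param x training matrix, samples in rows.
#' @return object of class `"feature_scaler"` with fields `feature_ids`,
#'   `min`, `max`.
#' @export
fit_minmax_scaler <- function(x) {
  validate_omics(x)
  if (nrow(x) < 1L) stop("scaler needs at least one sample", call. = FALSE)
  structure(list(feature_ids = colnames(x),
                 min = apply(x, 2L, min),
                 max = apply(x, 2L, max)),
            class = "feature_scaler")
}

check_scaler_ids <- function(x, scaler) {
  if (!identical(colnames(x), scaler$feature_ids)) {
    stop("feature ids do not match the scaler", call. = FALSE)
  }
}

#' Scale a matrix to \[0, 1\] with a fitted (or freshly fitted) scaler
#'
#' Constant features map to 0.5; out-of-range values in apply mode are
#' clamped to \[0, 1\].
#'
#' @param x matrix to scale.
#' @param scaler a `feature_scaler`, or `NULL` to fit on `x`.
#' @return list with `values` (scaled matrix) and `scaler`.
#' @export
minmax_scale <- function(x, scaler = NULL) {
  validate_omics(x)
  if (is.null(scaler)) scaler <- fit_minmax_scaler(x)
  check_scaler_ids(x, scaler)
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  scaled <- sweep(sweep(x, 2L, scaler$min, "-"), 2L, rng, "/")
  scaled[, const] <- 0.5
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  list(values = scaled, scaler = scaler)
}

#' Invert a min-max scaling back to the original feature scale
#'
#' @param scaled matrix of values in \[0, 1\].
#' @param scaler the `feature_scaler` used to scale.
#' @return matrix on the original scale.
#' @export
minmax_invert <- function(scaled, scaler) {
  validate_omics(scaled)
  check_scaler_ids(scaled, scaler)
  rng <- scaler$max - scaler$min
  sweep(sweep(scaled, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Serialize a feature scaler to a delimited table
#'
#' Three columns: feature id, min, max — keeps model checkpoints portable.
#'
#' @param scaler a `feature_scaler`.
#' @param path output path.
#' @export
write_scaler <- function(scaler, path) {
  data.table::fwrite(data.frame(feature_id = scaler$feature_ids,
                                min = scaler$min, max = scaler$max),
                     path, sep = "\t")
  invisible(path)
}

#' Read a feature scaler written by [write_scaler()]
#' @param path file path.
#' @return a `feature_scaler`.
#' @export
read_scaler <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  structure(list(feature_ids = as.character(tab$feature_id),
                 min = stats::setNames(as.numeric(tab$min), tab$feature_id),
                 max = stats::setNames(as.numeric(tab$max), tab$feature_id)),
            class = "feature_scaler")
}
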