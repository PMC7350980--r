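#' Construct a labeled sample-by-feature omics matrix
#'
#' The universal data carrier of the package: a plain numeric matrix with
#' unique sample ids on the rows and unique feature ids on the columns.
#' Methylation blocks hold CpG beta values in \[0, 1\]; expression blocks
#' hold gene values on the raw-count or log2(G+1) scale.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of row ids (defaults to `rownames(values)`).
#' @param feature_ids character vector of column ids (defaults to `colnames(values)`).
#' @param allow_na allow missing cells (used only before NA-site filtering).
#' @return the validated matrix with dimnames set, invisibly classed as
#'   `"omics_matrix"` for printing; it remains an ordinary base matrix.
#' @export
omics_matrix <- function(values,
                         sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         allow_na = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample and feature ids are required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of `sample_ids` must equal nrow(values)", call. = FALSE)
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length of `feature_ids` must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  if (!allow_na && anyNA(values)) {
    stop("matrix contains missing values (use allow_na = TRUE before filtering)",
         call. = FALSE)
  }
  if (any(is.infinite(values))) stop("matrix contains non-finite values", call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_ids)
  values
}

# Validate an existing matrix as an omics matrix; returns it unchanged.
validate_omics <- function(x, what = "matrix", allow_na = FALSE) {
  omics_matrix(x, allow_na = allow_na)
  x
}

#' Construct a survival record table
#'
#' @param sample_id character sample ids.
#' @param time positive follow-up times in days.
#' @param event 1 = death observed, 0 = censored.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
survival_records <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in survival records", call. = FALSE)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id)) {
    stop("sample_id, time and event must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all survival times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1", call. = FALSE)
  data.frame(sample_id = sample_id, time = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

#' Align methylation, expression and survival blocks into one cohort
#'
#' Keeps the intersection of sample ids present in all three blocks, sorted
#' lexicographically, and drops the rest (counts are reported via `message()`).
#'
#' @param meth methylation omics matrix (beta values in \[0, 1\]).
#' @param expr expression omics matrix.
#' @param survival data.frame from [survival_records()].
#' @param cohort_id cohort label.
#' @return an object of class `"paired_cohort"`: a list with elements
#'   `cohort_id`, `methylation`, `expression`, `survival`, all carrying the
#'   same samples in the same order.
#' @export
align_paired <- function(meth, expr, survival, cohort_id) {
  validate_omics(meth)
  validate_omics(expr)
  if (min(meth) < 0 || max(meth) > 1) {
    stop("methylation beta values must lie in [0, 1]", call. = FALSE)
  }
  common <- Reduce(intersect, list(rownames(meth), rownames(expr), survival$sample_id))
  if (length(common) == 0L) {
    stop("no samples shared by methylation, expression and survival blocks", call. = FALSE)
  }
  common <- sort(common)
  dropped <- length(union(union(rownames(meth), rownames(expr)), survival$sample_id)) -
    length(common)
  message(sprintf("cohort %s: kept %d samples, dropped %d without all three blocks",
                  cohort_id, length(common), dropped))
  surv <- survival[match(common, survival$sample_id), , drop = FALSE]
  rownames(surv) <- NULL
  structure(list(cohort_id = as.character(cohort_id),
                 methylation = meth[common, , drop = FALSE],
                 expression = expr[common, , drop = FALSE],
                 survival = surv),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort '%s': %d samples, %d CpG sites, %d genes, %d events\n",
              x$cohort_id, nrow(x$methylation), ncol(x$methylation),
              ncol(x$expression), sum(x$survival$event)))
  invisible(x)
}

#' Build seeded train/test partitions at a block-missing rate
#'
#' Each replicate marks `round((1 - missing_rate) * n)` samples (rounding
#' half away from zero) as the training set — samples whose expression is
#' retained — and the remainder as the test set whose expression block is
#' treated as missing. Replicate `i` draws without replacement under seed
#' `base_seed + i`.
#'
#' @param cohort a `paired_cohort`.
#' @param missing_rate fraction of samples whose expression block is missing,
#'   in (0, 1).
#' @param n_replicates number of independent partitions.
#' @param base_seed integer; replicate i uses seed `base_seed + i`.
#' @return list of `"missingness_plan"` objects with fields `missing_rate`,
#'   `replicate_seed`, `train_ids`, `test_ids`.
#' @export
make_missingness_plans <- function(cohort, missing_rate, n_replicates, base_seed) {
  stopifnot(inherits(cohort, "paired_cohort"))
  stop_if_not_scalar_number(missing_rate, "missing_rate")
  if (missing_rate <= 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  ids <- rownames(cohort$methylation)
  n <- length(ids)
  n_train <- as.integer(round_half_up((1 - missing_rate) * n))
  if (n_train < 2) {
    stop(sprintf("training set of size %d (< 2) at missing rate %.2f", n_train, missing_rate),
         call. = FALSE)
  }
  lapply(seq_len(n_replicates), function(i) {
    seed <- as.integer(base_seed + i)
    train <- with_rng_seed(seed, sample(ids, n_train, replace = FALSE))
    structure(list(missing_rate = missing_rate,
                   replicate_seed = seed,
                   train_ids = sort(train),
                   test_ids = sort(setdiff(ids, train))),
              class = "missingness_plan")
  })
}
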