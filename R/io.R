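#' Read a delimited omics table
#'
#' Reads a tab-separated table with a header row and an id column into a
#' sample-by-feature omics matrix. Files may store samples in rows or
#' features in rows; the returned matrix is always samples-in-rows.
#' Cells equal to `na_token` become `NA` (never silently 0); any other
#' non-numeric cell is an error.
#'
#' @param path file path.
#' @param orientation `"samples-in-rows"` (default) or `"features-in-rows"`.
#' @param na_token string treated as missing; default `"NA"`.
#' @param sep field separator, default tab.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_omics_table <- function(path,
                             orientation = c("samples-in-rows", "features-in-rows"),
                             na_token = "NA",
                             sep = "\t") {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                          na.strings = NULL, data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L) stop("table needs an id column and at least one data column", call. = FALSE)
  row_ids <- as.character(dt[[1L]])
  col_ids <- colnames(dt)[-1L]
  if (anyDuplicated(row_ids)) stop("duplicate row ids in ", path, call. = FALSE)
  if (anyDuplicated(col_ids)) stop("duplicate column ids in ", path, call. = FALSE)
  body <- as.matrix(dt[, -1L, drop = FALSE])
  is_na <- body == na_token
  num <- suppressWarnings(as.numeric(body))
  bad <- !is_na & is.na(num)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf("non-numeric cell '%s' (not the NA token '%s') in %s",
                 body[idx], na_token, path), call. = FALSE)
  }
  num[is_na] <- NA_real_
  m <- matrix(num, nrow = nrow(body), ncol = ncol(body),
              dimnames = list(row_ids, col_ids))
  if (orientation == "features-in-rows") m <- t(m)
  omics_matrix(m, allow_na = TRUE)
}

#' Write an omics matrix as a delimited table
#'
#' Inverse of [read_omics_table()]: values are written at full precision so
#' that write-then-read round-trips exactly.
#'
#' @param x sample-by-feature numeric matrix.
#' @param path output path.
#' @param orientation layout to write; default samples-in-rows.
#' @param na_token string written for `NA` cells.
#' @param sep field separator, default tab.
#' @param id_header name of the id column.
#' @export
write_omics_table <- function(x, path,
                              orientation = c("samples-in-rows", "features-in-rows"),
                              na_token = "NA",
                              sep = "\t",
                              id_header = "id") {
  orientation <- match.arg(orientation)
  validate_omics(x, allow_na = TRUE)
  if (orientation == "features-in-rows") x <- t(x)
  body <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  body[is.na(x)] <- na_token
  out <- data.frame(rownames(x), body, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c(id_header, colnames(x))
  data.table::fwrite(out, path, sep = sep, quote = FALSE, na = na_token)
  invisible(path)
}

#' Write one paired cohort to a directory
#'
#' Writes `methylation.tsv`, `expression.tsv` (samples in rows) and
#' `survival.tsv` in the delimited format [read_omics_table()] accepts.
#'
#' @param cohort a `paired_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_table(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_omics_table(cohort$expression, file.path(dir, "expression.tsv"))
  data.table::fwrite(cohort$survival, file.path(dir, "survival.tsv"), sep = "\t")
  invisible(dir)
}

#' Read one paired cohort from a directory written by [write_cohort()]
#'
#' @param dir directory containing `methylation.tsv`, `expression.tsv`,
#'   `survival.tsv`.
#' @param cohort_id cohort label; defaults to the directory name.
#' @return a `paired_cohort`.
#' @export
read_cohort <- function(dir, cohort_id = basename(dir)) {
  meth <- read_omics_table(file.path(dir, "methylation.tsv"))
  expr <- read_omics_table(file.path(dir, "expression.tsv"))
  surv <- data.table::fread(file.path(dir, "survival.tsv"), data.table = FALSE)
  align_paired(meth, expr,
               survival_records(surv$sample_id, surv$time, surv$event),
               cohort_id)
}
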