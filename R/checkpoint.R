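#' Save a trained imputer as a plain-text checkpoint directory
#'
#' Layout: `config.yaml` (network configuration), `W1.tsv`, `b1.tsv`,
#' `W2.tsv`, `b2.tsv` (parameter arrays at full precision), `scaler.tsv`
#' (per-gene min/max), `history.tsv` (per-epoch training loss). Checkpoints
#' reload exactly across runs with [read_checkpoint()].
#'
#' @param model a `trained_imputer`.
#' @param dir checkpoint directory (created if absent).
#' @export
write_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "trained_imputer"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(model$config), file.path(dir, "config.yaml"))
  write_mat <- function(x, name) {
    data.table::fwrite(data.table::as.data.table(x), file.path(dir, name),
                       sep = "\t", col.names = FALSE)
  }
  write_mat(model$params$W1, "W1.tsv")
  write_mat(matrix(model$params$b1, nrow = 1), "b1.tsv")
  write_mat(model$params$W2, "W2.tsv")
  write_mat(matrix(model$params$b2, nrow = 1), "b2.tsv")
  write_scaler(model$output_scaler, file.path(dir, "scaler.tsv"))
  data.table::fwrite(data.frame(epoch = seq_along(model$history), loss = model$history),
                     file.path(dir, "history.tsv"), sep = "\t")
  writeLines(model$input_ids, file.path(dir, "input_ids.txt"))
  writeLines(model$output_ids, file.path(dir, "output_ids.txt"))
  invisible(dir)
}

#' Reload a checkpoint written by [write_checkpoint()]
#'
#' @param dir checkpoint directory.
#' @return a `trained_imputer`.
#' @export
read_checkpoint <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(network_config, cfg)
  read_mat <- function(name) {
    as.matrix(data.table::fread(file.path(dir, name), sep = "\t", header = FALSE))
  }
  params <- structure(list(W1 = unname(read_mat("W1.tsv")),
                           b1 = as.numeric(read_mat("b1.tsv")),
                           W2 = unname(read_mat("W2.tsv")),
                           b2 = as.numeric(read_mat("b2.tsv"))),
                      class = "mlp_parameters")
  history <- data.table::fread(file.path(dir, "history.tsv"), data.table = FALSE)$loss
  new_trained_imputer(config, params, read_scaler(file.path(dir, "scaler.tsv")),
                      history %||% numeric(0),
                      readLines(file.path(dir, "input_ids.txt")),
                      readLines(file.path(dir, "output_ids.txt")))
}
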