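#' Network configuration for the methylation-to-expression imputer
#'
#' A single-hidden-layer fully connected network maps a sample's CpG beta
#' values to its gene-expression vector. The sigmoid activation is applied to
#' the hidden and output layers, so expression targets must be min-max scaled
#' to \[0, 1\]. Training minimizes the root-mean-square error between
#' predicted and measured (scaled) expression with the Adam optimizer.
#' Defaults follow the tuned values used throughout the package: one hidden
#' layer of 4000 units, learning rate 1e-4, 300 pretraining epochs at batch
#' 128 and 150 fine-tuning epochs at batch 16; the small fine-tuning batch
#' suits the small training sets left at high missing rates.
#'
#' @param input_dim number of CpG sites.
#' @param output_dim number of genes.
#' @param hidden_dim hidden layer width (default 4000; desk-scale runs use
#'   much smaller widths).
#' @param activation only `"sigmoid"` is supported.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param pretrain_epochs,finetune_epochs epoch counts (defaults 300 / 150).
#' @param pretrain_batch,finetune_batch mini-batch sizes (defaults 128 / 16).
#' @param seed integer seed for weight initialization and epoch shuffling.
#' @return object of class `"network_config"`.
#' @export
network_config <- function(input_dim, output_dim,
                           hidden_dim = 4000,
                           activation = "sigmoid",
                           learning_rate = 1e-4,
                           pretrain_epochs = 300,
                           finetune_epochs = 150,
                           pretrain_batch = 128,
                           finetune_batch = 16,
                           seed = 1L) {
  for (nm in c("input_dim", "output_dim", "hidden_dim")) {
    stop_if_not_scalar_number(get(nm), nm, min = 1)
  }
  if (!identical(activation, "sigmoid")) {
    stop("only the sigmoid activation is supported", call. = FALSE)
  }
  stop_if_not_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  for (nm in c("pretrain_epochs", "finetune_epochs")) {
    if (get(nm) < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  for (nm in c("pretrain_batch", "finetune_batch")) {
    if (get(nm) < 1) stop(sprintf("`%s` must be >= 1", nm), call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 activation = activation,
                 learning_rate = learning_rate,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 pretrain_batch = as.integer(pretrain_batch),
                 finetune_batch = as.integer(finetune_batch),
                 seed = as.integer(seed)),
            class = "network_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize network parameters
#'
#' Weights are drawn Glorot-uniform (limit `sqrt(6 / (fan_in + fan_out))`)
#' under the config seed; biases start at zero. Deterministic per seed.
#'
#' @param config a `network_config`.
#' @return object of class `"mlp_parameters"`: list of `W1`, `b1`, `W2`, `b2`.
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  p <- config$input_dim; h <- config$hidden_dim; q <- config$output_dim
  with_rng_seed(config$seed, {
    lim1 <- sqrt(6 / (p + h))
    lim2 <- sqrt(6 / (h + q))
    structure(list(W1 = matrix(stats::runif(p * h, -lim1, lim1), p, h),
                   b1 = numeric(h),
                   W2 = matrix(stats::runif(h * q, -lim2, lim2), h, q),
                   b2 = numeric(q)),
              class = "mlp_parameters")
  })
}

# Forward pass on scaled inputs; returns hidden and output activations.
mlp_forward <- function(params, X) {
  H <- sigmoid(sweep(X %*% params$W1, 2L, params$b1, "+"))
  Y <- sigmoid(sweep(H %*% params$W2, 2L, params$b2, "+"))
  list(H = H, Y = Y)
}

# Loss over a matrix of targets: RMSE over all entries,
# sqrt(mean((y - y0)^2)); on a single sample this is the per-sample
# over-genes RMSE the training objective is defined by.
rmse_loss <- function(pred, target) sqrt(mean((pred - target)^2))

#' Train the network by mini-batch Adam on the RMSE loss
#'
#' Samples are reshuffled every epoch with a seeded generator; the last
#' incomplete mini-batch is used, not dropped. Adam uses beta1 = 0.9,
#' beta2 = 0.999, epsilon = 1e-8 with bias correction. The returned history
#' holds the full-training-set RMSE after each epoch.
#'
#' @param params starting `mlp_parameters` (not modified).
#' @param meth training methylation matrix (inputs, samples in rows).
#' @param expr_scaled training expression matrix scaled to \[0, 1\].
#' @param epochs number of passes over the data (0 = return unchanged).
#' @param batch mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param seed shuffle seed.
#' @return list with `params` (trained) and `history` (length `epochs`).
#' @export
train_network <- function(params, meth, expr_scaled, epochs, batch, learning_rate, seed) {
  stopifnot(inherits(params, "mlp_parameters"))
  if (!identical(rownames(meth), rownames(expr_scaled))) {
    stop("methylation and expression training blocks are not aligned", call. = FALSE)
  }
  if (min(expr_scaled) < 0 || max(expr_scaled) > 1) {
    stop("expression targets must be scaled to [0, 1]", call. = FALSE)
  }
  n <- nrow(meth)
  if (epochs == 0L) return(list(params = params, history = numeric(0)))

  W <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2)
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- numeric(epochs)

  with_rng_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch)
      for (s in starts) {
        idx <- ord[s:min(s + batch - 1L, n)]
        Xb <- meth[idx, , drop = FALSE]
        Yb <- expr_scaled[idx, , drop = FALSE]
        fwd <- mlp_forward(W, Xb)
        E <- fwd$Y - Yb
        L <- sqrt(mean(E^2))
        if (!is.finite(L)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
        }
        if (L == 0) next
        # dL/dA2 for L = sqrt(mean(E^2)) over B*q entries
        dA2 <- (E / (length(E) * L)) * fwd$Y * (1 - fwd$Y)
        g <- list(W1 = NULL, b1 = NULL, W2 = crossprod(fwd$H, dA2), b2 = colSums(dA2))
        dH <- tcrossprod(dA2, W$W2) * fwd$H * (1 - fwd$H)
        g$W1 <- crossprod(Xb, dH)
        g$b1 <- colSums(dH)
        t_step <- t_step + 1L
        for (nm in names(W)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
          m_hat <- m[[nm]] / (1 - beta1^t_step)
          v_hat <- v[[nm]] / (1 - beta2^t_step)
          W[[nm]] <- W[[nm]] - learning_rate * m_hat / (sqrt(v_hat) + eps)
        }
      }
      history[epoch] <- rmse_loss(mlp_forward(W, meth)$Y, expr_scaled)
      if (!is.finite(history[epoch])) {
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      }
    }
  })
  list(params = structure(W, class = "mlp_parameters"), history = history)
}

new_trained_imputer <- function(config, params, scaler, history, input_ids, output_ids) {
  structure(list(config = config, params = params, output_scaler = scaler,
                 history = history, input_ids = input_ids, output_ids = output_ids),
            class = "trained_imputer")
}

#' @export
print.trained_imputer <- function(x, ...) {
  cat(sprintf("trained_imputer: %d CpGs -> %d hidden -> %d genes, %d epochs trained (final loss %.4g)\n",
              x$config$input_dim, x$config$hidden_dim, x$config$output_dim,
              length(x$history),
              if (length(x$history)) x$history[length(x$history)] else NA_real_))
  invisible(x)
}

# Concatenate the methylation/expression blocks of several cohorts.
pool_cohorts <- function(cohorts) {
  meth <- do.call(rbind, lapply(cohorts, function(co) co$methylation))
  expr <- do.call(rbind, lapply(cohorts, function(co) co$expression))
  list(meth = meth, expr = expr)
}

#' Pretrain a pan-cohort imputation model, excluding the target cohort
#'
#' Pools all cohorts except the target into one training corpus, fits the
#' output min-max scaler on that corpus (frozen through any later
#' fine-tuning) and trains for `pretrain_epochs` at `pretrain_batch`.
#'
#' @param cohorts list of `paired_cohort` objects with matching feature ids.
#' @param target_cohort_id cohort to leave out.
#' @param config a `network_config`.
#' @return a `trained_imputer`.
#' @export
pretrain_pan_cancer <- function(cohorts, target_cohort_id, config) {
  ids <- vapply(cohorts, function(co) co$cohort_id, character(1))
  if (!target_cohort_id %in% ids) stop("target cohort not in cohort list", call. = FALSE)
  rest <- cohorts[ids != target_cohort_id]
  if (length(rest) == 0L) {
    stop("pretraining needs at least one cohort besides the target", call. = FALSE)
  }
  pooled <- pool_cohorts(rest)
  scaled <- minmax_scale(pooled$expr)
  params <- init_network(config)
  fit <- train_network(params, pooled$meth, scaled$values,
                       epochs = config$pretrain_epochs,
                       batch = config$pretrain_batch,
                       learning_rate = config$learning_rate,
                       seed = config$seed)
  new_trained_imputer(config, fit$params, scaled$scaler, fit$history,
                      colnames(pooled$meth), colnames(pooled$expr))
}

#' Fine-tune a pretrained model on the target cohort's training samples
#'
#' Continues training of all layers (none frozen) for `finetune_epochs` at
#' `finetune_batch`, reusing the pretrained model's frozen output scaler.
#' The pretrained object is left unmodified.
#'
#' @param pretrained a `trained_imputer`.
#' @param target_train_meth,target_train_expr aligned training blocks of the
#'   target cohort (expression on the log2 scale, unscaled).
#' @param config optional `network_config` override; defaults to the
#'   pretrained model's config.
#' @return a new `trained_imputer`.
#' @export
fine_tune <- function(pretrained, target_train_meth, target_train_expr,
                      config = pretrained$config) {
  stopifnot(inherits(pretrained, "trained_imputer"))
  if (!identical(colnames(target_train_meth), pretrained$input_ids) ||
      !identical(colnames(target_train_expr), pretrained$output_ids)) {
    stop("target feature ids do not match the pretrained model", call. = FALSE)
  }
  scaled <- minmax_scale(target_train_expr, pretrained$output_scaler)
  fit <- train_network(pretrained$params, target_train_meth, scaled$values,
                       epochs = config$finetune_epochs,
                       batch = config$finetune_batch,
                       learning_rate = config$learning_rate,
                       seed = config$seed + 1L)
  new_trained_imputer(config, fit$params, pretrained$output_scaler, fit$history,
                      pretrained$input_ids, pretrained$output_ids)
}

#' Impute gene expression from methylation with a trained model
#'
#' Forward pass followed by inversion of the output scaler; deterministic
#' given the parameters. Outputs land inside each gene's scaler range, a
#' consequence of the sigmoid output layer.
#'
#' @param model a `trained_imputer`.
#' @param meth methylation matrix with the model's input feature ids.
#' @return imputed expression matrix (log2 scale), genes = model output ids.
#' @export
impute_expression <- function(model, meth) {
  stopifnot(inherits(model, "trained_imputer"))
  if (!identical(colnames(meth), model$input_ids)) {
    stop("methylation feature ids do not match the model inputs", call. = FALSE)
  }
  pred <- mlp_forward(model$params, meth)$Y
  dimnames(pred) <- list(rownames(meth), model$output_ids)
  minmax_invert(pred, model$output_scaler)
}

#' Run one neural-imputation variant on a missingness plan
#'
#' Variants:
#' * `"transfer"` — pretrain on all other cohorts, fine-tune on the plan's
#'   training samples, impute the plan's test samples;
#' * `"self"` — train from random initialization on the plan's training
#'   samples only (pretraining epoch count and batch size);
#' * `"pretrain"` — apply the pan-cohort model directly, no fine-tuning.
#'
#' @param variant one of `"transfer"`, `"self"`, `"pretrain"`.
#' @param cohorts list of `paired_cohort` objects.
#' @param target_id the cohort the plan partitions.
#' @param plan a `missingness_plan` for the target cohort.
#' @param config a `network_config`.
#' @param pretrained optionally a precomputed pan-cohort `trained_imputer`
#'   (excluding the target), reused across plans for speed.
#' @return imputed expression matrix for the plan's test samples.
#' @export
run_variant <- function(variant, cohorts, target_id, plan, config, pretrained = NULL) {
  variant <- match.arg(variant, c("transfer", "self", "pretrain"))
  ids <- vapply(cohorts, function(co) co$cohort_id, character(1))
  target <- cohorts[[match(target_id, ids)]]
  if (!all(c(plan$train_ids, plan$test_ids) %in% rownames(target$methylation))) {
    stop("plan sample ids are not all in the target cohort", call. = FALSE)
  }
  test_meth <- target$methylation[plan$test_ids, , drop = FALSE]
  if (variant == "self") {
    train_meth <- target$methylation[plan$train_ids, , drop = FALSE]
    train_expr <- target$expression[plan$train_ids, , drop = FALSE]
    scaled <- minmax_scale(train_expr)
    fit <- train_network(init_network(config), train_meth, scaled$values,
                         epochs = config$pretrain_epochs,
                         batch = config$pretrain_batch,
                         learning_rate = config$learning_rate,
                         seed = config$seed)
    model <- new_trained_imputer(config, fit$params, scaled$scaler, fit$history,
                                 colnames(train_meth), colnames(train_expr))
    return(impute_expression(model, test_meth))
  }
  if (is.null(pretrained)) {
    pretrained <- pretrain_pan_cancer(cohorts, target_id, config)
  }
  if (variant == "pretrain") {
    return(impute_expression(pretrained, test_meth))
  }
  tuned <- fine_tune(pretrained,
                     target$methylation[plan$train_ids, , drop = FALSE],
                     target$expression[plan$train_ids, , drop = FALSE],
                     config)
  impute_expression(tuned, test_meth)
}
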