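# forward pass of the sigmoid MLP written out independently of the package
ref_forward <- function(W1, b1, W2, b2, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(x %*% W1 + matrix(b1, nrow(x), length(b1), byrow = TRUE))
  sig(h %*% W2 + matrix(b2, nrow(x), length(b2), byrow = TRUE))
}

test_that("initialization is seeded, symmetric and correctly shaped", {
  cfg <- network_config(input_dim = 30, output_dim = 10, hidden_dim = 4000,
                        seed = 9)
  p1 <- init_network(cfg)
  p2 <- init_network(cfg)
  expect_identical(p1, p2)
  expect_equal(dim(p1$W1), c(30, 4000))
  expect_equal(dim(p1$W2), c(4000, 10))
  expect_true(all(p1$b1 == 0) && all(p1$b2 == 0))
  # symmetric (mean-zero) Glorot draw: sample mean within 3 standard errors
  lim <- sqrt(6 / (30 + 4000))
  se <- (2 * lim / sqrt(12)) / sqrt(length(p1$W1))
  expect_lt(abs(mean(p1$W1)), 3 * se)
  # distinct seeds give distinct draws
  expect_false(identical(p1$W1, init_network(network_config(30, 10, 4000, seed = 10))$W1))
})

test_that("zero epochs returns parameters unchanged with empty history", {
  x <- tiny_matrix(4, 3, prefix = "cg")
  y <- tiny_matrix(4, 2, seed = 2, prefix = "g")
  cfg <- small_net(3, 2)
  p0 <- init_network(cfg)
  fit <- train_network(p0, x, y, epochs = 0, batch = 2, learning_rate = 1e-3, seed = 1)
  expect_identical(fit$params, p0)
  expect_length(fit$history, 0)
})

test_that("one Adam step on a 1-1-1 network matches a numeric-gradient oracle", {
  params <- structure(list(W1 = matrix(0.3, 1, 1), b1 = 0.05,
                           W2 = matrix(-0.2, 1, 1), b2 = 0.1),
                      class = "mlp_parameters")
  x <- matrix(0.7, 1, 1, dimnames = list("s1", "cg1"))
  y <- matrix(0.4, 1, 1, dimnames = list("s1", "g1"))
  lr <- 0.01
  fit <- train_network(params, x, y, epochs = 1, batch = 1,
                       learning_rate = lr, seed = 1)

  # independent route: finite-difference gradient of the per-sample RMSE,
  # then one Adam update (beta1 0.9, beta2 0.999, eps 1e-8, bias-corrected)
  loss_at <- function(theta) {
    sqrt(mean((ref_forward(matrix(theta[1], 1, 1), theta[2],
                           matrix(theta[3], 1, 1), theta[4], x) - y)^2))
  }
  theta <- c(0.3, 0.05, -0.2, 0.1)
  g <- numeric(4)
  eps_fd <- 1e-7
  for (i in 1:4) {
    up <- theta; up[i] <- up[i] + eps_fd
    dn <- theta; dn[i] <- dn[i] - eps_fd
    g[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps_fd)
  }
  m_hat <- g                      # m / (1 - beta1^1)
  v_hat <- g^2                    # v / (1 - beta2^1)
  expected <- theta - lr * m_hat / (sqrt(v_hat) + 1e-8)
  got <- c(fit$params$W1, fit$params$b1, fit$params$W2, fit$params$b2)
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("training reduces the loss on sigmoid-generated data", {
  withr::local_seed(31)
  n <- 200; p <- 12; h <- 8; q <- 6
  cfg <- network_config(p, q, hidden_dim = h, learning_rate = 1e-2,
                        pretrain_epochs = 150, pretrain_batch = 32, seed = 4)
  true_p <- init_network(network_config(p, q, hidden_dim = h, seed = 99))
  X <- matrix(runif(n * p), n, p, dimnames = list(sprintf("s%d", 1:n), sprintf("cg%d", 1:p)))
  Y <- ref_forward(true_p$W1, true_p$b1, true_p$W2, true_p$b2, X) +
    matrix(rnorm(n * q, 0, 0.02), n, q)
  Y <- pmin(pmax(Y, 0), 1)
  colnames(Y) <- sprintf("g%d", 1:q)
  fit <- train_network(init_network(cfg), X, Y, epochs = 150, batch = 32,
                       learning_rate = 1e-2, seed = 4)
  expect_true(all(is.finite(fit$history)))
  expect_lt(fit$history[length(fit$history)], 0.5 * fit$history[1])
  # determinism of the whole trained model
  fit2 <- train_network(init_network(cfg), X, Y, epochs = 150, batch = 32,
                        learning_rate = 1e-2, seed = 4)
  expect_identical(fit$params, fit2$params)
})

test_that("imputation equals hand matrix arithmetic plus scaler inversion", {
  params <- structure(list(W1 = matrix(c(0.5, -0.3), 2, 1), b1 = 0.1,
                           W2 = matrix(0.8, 1, 1), b2 = -0.2),
                      class = "mlp_parameters")
  scaler <- structure(list(feature_ids = "g1", min = c(g1 = 2), max = c(g1 = 6)),
                      class = "feature_scaler")
  cfg <- network_config(2, 1, hidden_dim = 1)
  model <- panimpute:::new_trained_imputer(cfg, params, scaler, numeric(0),
                                           c("cg1", "cg2"), "g1")
  meth <- matrix(c(0.2, 0.9), 1, 2, dimnames = list("s1", c("cg1", "cg2")))
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(0.2 * 0.5 + 0.9 * (-0.3) + 0.1)
  y_scaled <- sig(h * 0.8 - 0.2)
  expect_equal(unname(impute_expression(model, meth)[1, 1]), 2 + 4 * y_scaled)
  # deterministic, and bounded by the scaler range
  expect_identical(impute_expression(model, meth), impute_expression(model, meth))
  expect_true(impute_expression(model, meth) >= 2 && impute_expression(model, meth) <= 6)
  colnames(meth) <- c("x", "y")
  expect_error(impute_expression(model, meth), "feature ids")
})

test_that("pretraining excludes the target cohort and fine-tuning respects epochs", {
  gen <- small_cohorts(seed = 21)
  cfg <- small_net(30, 20, epochs = 10)
  pre <- pretrain_pan_cancer(gen$cohorts, "C2", cfg)
  # corpus excludes C2: scaler fitted on C1+C3 expression only
  pooled <- rbind(gen$cohorts[[1]]$expression, gen$cohorts[[3]]$expression)
  expect_equal(unname(pre$output_scaler$min), unname(apply(pooled, 2, min)))
  expect_error(pretrain_pan_cancer(gen$cohorts[2], "C2", cfg), "at least one cohort")

  # finetune_epochs = 0 leaves predictions identical to the pretrained model
  cfg0 <- network_config(30, 20, hidden_dim = 8, finetune_epochs = 0, seed = 1)
  target <- gen$cohorts[[2]]
  tuned <- fine_tune(pre, target$methylation, target$expression, cfg0)
  expect_identical(impute_expression(tuned, target$methylation),
                   impute_expression(pre, target$methylation))
  # fine-tuning reduces the target-set loss relative to the pretrained model
  tuned2 <- fine_tune(pre, target$methylation, target$expression, cfg)
  scaled <- minmax_scale(target$expression, pre$output_scaler)$values
  loss_pre <- sqrt(mean((panimpute:::mlp_forward(pre$params, target$methylation)$Y - scaled)^2))
  expect_lte(tuned2$history[length(tuned2$history)], loss_pre)
  # the pretrained object was not modified
  expect_equal(unname(pre$output_scaler$min), unname(apply(pooled, 2, min)))
})

test_that("variants reduce to each other as constructed", {
  gen <- small_cohorts(seed = 22)
  co <- gen$cohorts[[1]]
  plan <- make_missingness_plans(co, 0.5, 1, base_seed = 5)[[1]]
  cfg <- small_net(30, 20, epochs = 8)
  pre <- pretrain_pan_cancer(gen$cohorts, "C1", cfg)
  # transfer with 0 fine-tuning epochs == pretrain-only
  cfg0 <- network_config(30, 20, hidden_dim = 8, learning_rate = 1e-2,
                         pretrain_epochs = 8, finetune_epochs = 0,
                         pretrain_batch = 16, seed = 1)
  expect_identical(run_variant("transfer", gen$cohorts, "C1", plan, cfg0, pretrained = pre),
                   run_variant("pretrain", gen$cohorts, "C1", plan, cfg0, pretrained = pre))
  # pretrain-only output ignores the plan's training rows
  plan2 <- make_missingness_plans(co, 0.5, 2, base_seed = 77)[[2]]
  shared <- intersect(plan$test_ids, plan2$test_ids)
  o1 <- run_variant("pretrain", gen$cohorts, "C1", plan, cfg, pretrained = pre)
  o2 <- run_variant("pretrain", gen$cohorts, "C1", plan2, cfg, pretrained = pre)
  expect_identical(o1[shared, ], o2[shared, ])
  expect_error(run_variant("bogus", gen$cohorts, "C1", plan, cfg), "arg")
})

test_that("checkpoints reload to an identical model", {
  gen <- small_cohorts(seed = 23, n_cohorts = 2, n = 20)
  cfg <- small_net(30, 20, epochs = 4)
  pre <- pretrain_pan_cancer(gen$cohorts, "C2", cfg)
  dir <- withr::local_tempdir()
  write_checkpoint(pre, dir)
  back <- read_checkpoint(dir)
  meth <- gen$cohorts[[2]]$methylation
  expect_equal(impute_expression(back, meth), impute_expression(pre, meth),
               tolerance = 1e-12)
  expect_equal(back$history, pre$history)
})

test_that("the pan-cohort model beats mean imputation on shared-structure data", {
  # no cohort-specific baseline shifts: structure is fully transferable
  cfg <- synthetic_config(n_cohorts = 3, samples_per_cohort = 80, n_cpg = 60,
                          n_gene = 40, n_driving_pairs = 12,
                          n_prognosis_genes = 4, baseline_shift_sd = 0, seed = 71)
  gen <- generate_multi_cohort(cfg)
  net <- network_config(60, 40, hidden_dim = 24, learning_rate = 1e-2,
                        pretrain_epochs = 120, pretrain_batch = 32, seed = 71)
  pre <- pretrain_pan_cancer(gen$cohorts, "C1", net)
  plan <- make_missingness_plans(gen$cohorts[[1]], 0.5, 1, base_seed = 710)[[1]]
  truth <- gen$cohorts[[1]]$expression[plan$test_ids, ]
  rmse_pre <- imputation_metrics(
    impute_expression(pre, gen$cohorts[[1]]$methylation[plan$test_ids, ]), truth)$rmse
  rmse_mean <- suppressWarnings(imputation_metrics(
    mean_impute(gen$cohorts[[1]]$expression[plan$train_ids, ], plan$test_ids),
    truth))$rmse
  expect_lt(rmse_pre, rmse_mean)
})

test_that("more shared structure makes the pan-cohort model transfer better", {
  rmse_at_alpha <- function(alpha, seed) {
    cfg <- synthetic_config(n_cohorts = 3, samples_per_cohort = 60, n_cpg = 50,
                            n_gene = 30, n_driving_pairs = 10,
                            n_prognosis_genes = 4, shared_fraction = alpha,
                            baseline_shift_sd = 0, seed = seed)
    gen <- generate_multi_cohort(cfg)
    net <- network_config(50, 30, hidden_dim = 16, learning_rate = 1e-2,
                          pretrain_epochs = 80, pretrain_batch = 32, seed = seed)
    pre <- pretrain_pan_cancer(gen$cohorts, "C1", net)
    plan <- make_missingness_plans(gen$cohorts[[1]], 0.9, 1, base_seed = seed)[[1]]
    truth <- gen$cohorts[[1]]$expression[plan$test_ids, ]
    imputation_metrics(
      impute_expression(pre, gen$cohorts[[1]]$methylation[plan$test_ids, ]),
      truth)$rmse
  }
  seeds <- c(81, 82, 83)
  lo <- mean(vapply(seeds, function(s) rmse_at_alpha(0.2, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) rmse_at_alpha(0.9, s), numeric(1)))
  expect_lte(hi, lo)
})
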