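test_that("positional encoding is deterministic, even-dimensional, distinct on the grid", {
  pe0 <- positional_encoding(0, 32)
  expect_equal(pe0[seq(1, 32, 2)], rep(0, 16)) # sin(0)
  expect_equal(pe0[seq(2, 32, 2)], rep(1, 16)) # cos(0)
  expect_identical(positional_encoding(44, 32), positional_encoding(44, 32))
  expect_error(positional_encoding(10, 31), "even")
  expect_error(positional_encoding(-1, 32), "non-negative")

  codes <- t(vapply(default_acquisition_daps(), positional_encoding,
                    numeric(32), dim = 32))
  d <- as.matrix(dist(codes))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("time point embeddings have dimension 32 and additive positional encoding", {
  cfg <- fast_config(T = 3)
  model <- harvshap:::init_model(cfg)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tpe <- encode_time_point(model, img, dap = 44)
  expect_length(tpe, 32)
  bare <- encode_time_point(model, img, dap = 44, include_positional = FALSE)
  expect_equal(tpe - bare, positional_encoding(44, 32))
  expect_error(encode_time_point(model, runif(10), dap = 44), "input_size")
})

test_that("the head hidden layer follows the T x 32 / lambda rule", {
  expect_equal(model_config(T = 11, lambda = 2)$head_hidden, 176)
  expect_equal(model_config(T = 8, lambda = 4)$head_hidden, 64)
  expect_equal(model_config(T = 5, lambda = 3)$head_hidden, floor(5 * 32 / 3))
  expect_error(model_config(T = 11, lambda = 2, backbone = "resnet18"), "tiny")
})

test_that("series classification is deterministic and order sensitive", {
  field <- fixture_field(n_plants = 10, seed = 3)
  cfg <- fast_config(T = 5)
  ds <- series_dataset(build_series(field$manifest, 5), cfg, field$dir)
  model <- harvshap:::init_model(cfg)

  s1 <- classify_series(model, ds)
  s2 <- classify_series(model, ds)
  expect_identical(s1, s2)
  expect_equal(ncol(s1), 2)

  # permuting two time points (with their days) relocates them in the
  # concatenated embedding, so scores must change
  ds_perm <- ds
  ds_perm$rows[, c(1, 4)] <- ds_perm$rows[, c(4, 1)]
  ds_perm$daps[, c(1, 4)] <- ds_perm$daps[, c(4, 1)]
  s3 <- classify_series(model, ds_perm)
  expect_gt(mean(abs(s3 - s1)), 1e-6)
})

test_that("every time point runs through one shared encoder", {
  cfg <- fast_config(T = 4)
  model <- harvshap:::init_model(cfg)
  # the model owns exactly one encoder parameter set; embeddings of the
  # same image at different positions differ only by the positional code
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  e_at_44 <- encode_time_point(model, img, 44, include_positional = FALSE)
  e_at_80 <- encode_time_point(model, img, 80, include_positional = FALSE)
  expect_identical(e_at_44, e_at_80)
  expect_named(model$params, c("W1", "b1", "W2", "b2", "U1", "c1", "U2", "c2"))
})

test_that("training learns planted signal, reproduces identically, and beats the null", {
  field <- fixture_field(n_plants = 60, seed = 2)
  cfg <- fast_config(T = 6)
  sp <- split_plants(field$manifest, val_frac = 0.25, seed = 2)
  ds_tr <- series_dataset(build_series(sp$train, 6), cfg, field$dir)
  ds_va <- series_dataset(build_series(sp$val, 6), cfg, field$dir)

  fit1 <- train_model(ds_tr, ds_va, cfg)
  fit2 <- train_model(ds_tr, ds_va, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  # binomial null: accuracy above 0.5 + 3 sigma on the validation count
  n <- ds_va$n
  best <- max(fit1$history$val_oaacc)
  expect_gt(best, 0.5 + 3 * sqrt(0.25 / n))

  preds <- predict_readiness(fit1$model, ds_va)
  expect_equal(nrow(preds), n)
  expect_true(all(preds$predicted %in% c("Ready", "Not-ready")))
})

test_that("gradients match finite differences on a tiny batch", {
  field <- fixture_field(n_plants = 6, seed = 5)
  cfg <- fast_config(T = 3)
  ds <- series_dataset(build_series(field$manifest, 3), cfg, field$dir)
  model <- harvshap:::init_model(cfg)
  params <- model$params
  rows <- ds$rows[1:4, , drop = FALSE]
  daps <- ds$daps[1:4, , drop = FALSE]
  labels <- ds$labels[1:4]

  loss_of <- function(p) {
    fwd <- harvshap:::forward_pass(p, cfg, ds$X, rows, daps, keep = TRUE)
    harvshap:::backward_pass(p, fwd, labels)$loss
  }
  fwd <- harvshap:::forward_pass(params, cfg, ds$X, rows, daps, keep = TRUE)
  grads <- harvshap:::backward_pass(params, fwd, labels)$grads
  eps <- 1e-5
  for (nm in c("W1", "W2", "U1", "U2", "c1", "c2")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      fd <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("hyperparameter tuning returns the best configuration deterministically", {
  field <- fixture_field(n_plants = 24, seed = 1)
  cfg <- model_config(T = 3, min_epochs = 6, patience = 3, max_epochs = 8)
  sp <- split_plants(field$manifest, val_frac = 0.25, seed = 1)
  ds_tr <- series_dataset(build_series(sp$train, 3), cfg, field$dir)
  ds_va <- series_dataset(build_series(sp$val, 3), cfg, field$dir)

  one <- tune_hyperparameters(ds_tr, ds_va, cfg, alphas = 1e-2, lambdas = 2)
  expect_equal(one$best_config$alpha, 1e-2)
  expect_equal(one$best_config$lambda, 2L)
  expect_equal(nrow(one$results), 1)

  grid <- tune_hyperparameters(ds_tr, ds_va, cfg,
                               alphas = c(1e-3, 1e-2), lambdas = c(2, 4))
  expect_equal(nrow(grid$results), 4)
  # the winner attains the maximum; ties break to smaller lambda then alpha
  best_acc <- max(grid$results$val_oaacc)
  winners <- grid$results[grid$results$val_oaacc == best_acc, ]
  winners <- winners[order(winners$lambda, winners$alpha), ]
  expect_equal(grid$best_config$lambda, as.integer(winners$lambda[1]))
  expect_equal(grid$best_config$alpha, winners$alpha[1])
  expect_error(tune_hyperparameters(ds_tr, ds_va, cfg, alphas = numeric(0)), "empty")
})

test_that("checkpoints round-trip through disk", {
  cfg <- fast_config(T = 3)
  model <- harvshap:::init_model(cfg)
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
})
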