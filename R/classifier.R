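# Time-series classifier.
#
# Architecture: every image of a series is mapped by one shared encoder to a
# 32-d embedding; a fixed sinusoidal positional encoding of the plant's age
# (DAP) is added, giving the time point embedding (TPE). The T TPEs are
# concatenated into the time series embedding (TSE, length T x 32), which a
# two-layer head (hidden size floor(T*32 / lambda), ReLU) maps to two class
# scores (Not-ready, Ready). The loss of a series is accumulated over all
# its images' forward passes through the shared encoder; one optimizer step
# is taken per batch.

#' Model and training configuration
#'
#' @param T Series length.
#' @param embedding_dim Per-image embedding size (32).
#' @param lambda Integer scaling factor for the head's hidden layer: hidden
#'   size is `floor(T * embedding_dim / lambda)` (tuning range 2..4).
#' @param alpha Weight decay of the Adam optimizer (tuning range 1e-3..1e-1).
#' @param learning_rate Adam learning rate. Default 1e-3, sized for the
#'   compact randomly initialised encoder trained here from scratch; with a
#'   large pretrained backbone a much smaller rate (1e-5) is customary.
#' @param batch_size Series per optimizer step (16).
#' @param scheduler_step,scheduler_gamma Step learning-rate schedule: the
#'   rate is multiplied by `scheduler_gamma` every `scheduler_step` epochs.
#' @param min_epochs Minimum number of training epochs before early
#'   stopping is considered (60).
#' @param patience Early stopping: training stops once validation overall
#'   accuracy has not improved by more than 1e-4 for this many epochs (10).
#' @param max_epochs Hard cap on epochs.
#' @param backbone Image encoder; `"tiny"` is a compact fully connected
#'   encoder on pooled grayscale input (the only backbone implemented).
#' @param input_size Side length of the pooled grayscale input grid fed to
#'   the encoder.
#' @param encoder_hidden Hidden width of the encoder.
#' @param seed Seed governing weight initialisation and batch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(T,
                         embedding_dim = 32L,
                         lambda = 2L,
                         alpha = 1e-3,
                         learning_rate = 1e-3,
                         batch_size = 16L,
                         scheduler_step = 20L,
                         scheduler_gamma = 0.1,
                         min_epochs = 60L,
                         patience = 10L,
                         max_epochs = 200L,
                         backbone = c("tiny", "resnet18"),
                         input_size = 16L,
                         encoder_hidden = 32L,
                         seed = 0L) {
  backbone <- match.arg(backbone)
  if (backbone == "resnet18") {
    abort(paste0(
      "The resnet18 backbone requires a deep-learning runtime that this ",
      "package does not ship; use backbone = \"tiny\"."
    ))
  }
  T <- as.integer(T)
  lambda <- as.integer(lambda)
  if (T < 1L) abort("`T` must be positive.")
  if (lambda < 1L) abort("`lambda` must be a positive integer.")
  if (alpha < 0) abort("`alpha` must be non-negative.")
  hidden <- (T * as.integer(embedding_dim)) %/% lambda
  if (hidden < 2L) abort("Head hidden size (T * embedding_dim / lambda) must be at least 2.")
  structure(
    list(T = T, embedding_dim = as.integer(embedding_dim), lambda = lambda,
         alpha = alpha, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         scheduler_step = as.integer(scheduler_step),
         scheduler_gamma = scheduler_gamma,
         min_epochs = as.integer(min_epochs), patience = as.integer(patience),
         max_epochs = as.integer(max_epochs), backbone = backbone,
         input_size = as.integer(input_size),
         encoder_hidden = as.integer(encoder_hidden),
         head_hidden = hidden, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> T = %d, backbone %s, lambda = %d (head hidden %d), alpha = %g\n",
              x$T, x$backbone, x$lambda, x$head_hidden, x$alpha))
  cat(sprintf("  lr %g (step %d, gamma %g), batch %d, epochs >= %d (patience %d), seed %d\n",
              x$learning_rate, x$scheduler_step, x$scheduler_gamma, x$batch_size,
              x$min_epochs, x$patience, x$seed))
  invisible(x)
}

#' Sinusoidal positional encoding of plant age
#'
#' Fixed (non-learned) code over the raw day-after-planting value:
#' `pe[2i-1] = sin(dap / 10000^((i-1)/(dim/2)))`,
#' `pe[2i] = cos(dap / 10000^((i-1)/(dim/2)))`.
#' Deterministic, and pairwise distinct over any realistic acquisition grid.
#'
#' @param dap Non-negative day after planting.
#' @param dim Even embedding dimension.
#' @return Numeric vector of length `dim`.
#' @export
positional_encoding <- function(dap, dim = 32L) {
  if (dim %% 2L != 0L) abort("`dim` must be even.")
  if (dap < 0) abort("`dap` must be non-negative.")
  half <- dim %/% 2L
  freq <- 1 / 10000^((seq_len(half) - 1) / half)
  pe <- numeric(dim)
  pe[seq(1, dim, by = 2)] <- sin(dap * freq)
  pe[seq(2, dim, by = 2)] <- cos(dap * freq)
  pe
}

# -- dataset ------------------------------------------------------------------

# Preprocess one image array: optional geometric ops, grayscale, block-mean
# pooling to g x g, normalisation to roughly [-1, 1].
preprocess_image <- function(img, ops, input_size) {
  if (length(ops)) img <- apply_image_ops(img, ops)
  m <- if (length(dim(img)) == 3L) {
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else {
    img
  }
  g <- input_size
  s <- nrow(m)
  if (s < g) abort(sprintf("Image side %d smaller than encoder input size %d.", s, g))
  f <- s %/% g
  if (f * g != s) m <- m[seq_len(f * g), seq_len(f * g), drop = FALSE]
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = g)       # pool rows
  m <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = g)) # pool cols
  as.vector((m - 0.5) / 0.5)
}

#' Materialise a list of series into an in-memory dataset
#'
#' Loads every referenced image once (per augmentation signature), applies
#' recorded geometric ops, converts to pooled grayscale features, and builds
#' the index structures used by training and inference. All series must
#' share one length `T`.
#'
#' @param samples List of `series_sample` objects.
#' @param config A [model_config()].
#' @param root Directory against which relative image paths are resolved.
#' @return An object of class `series_dataset`.
#' @export
series_dataset <- function(samples, config, root = ".") {
  if (!length(samples)) abort("No series to build a dataset from.")
  Ts <- vapply(samples, `[[`, integer(1), "T")
  if (length(unique(Ts)) != 1L) abort("All series in a dataset must share one length T.")
  if (Ts[1] != config$T) {
    abort(sprintf("Series length %d does not match config$T = %d.", Ts[1], config$T))
  }
  keys <- lapply(samples, function(s) paste0(s$image_paths, "|", paste(s$ops, collapse = "+")))
  uniq <- unique(unlist(keys))
  feat <- matrix(0, nrow = length(uniq), ncol = config$input_size^2)
  for (i in seq_along(uniq)) {
    parts <- strsplit(uniq[i], "|", fixed = TRUE)[[1]]
    pth <- parts[1]
    ops <- if (length(parts) > 1 && nzchar(parts[2])) strsplit(parts[2], "+", fixed = TRUE)[[1]] else character(0)
    full <- if (file.exists(pth)) pth else file.path(root, pth)
    if (!file.exists(full)) abort(sprintf("Image file not found: %s", full))
    feat[i, ] <- preprocess_image(png::readPNG(full), ops, config$input_size)
  }
  row_of <- setNames(seq_along(uniq), uniq)
  as_row_mat <- function(v) {
    if (is.null(dim(v))) matrix(v, ncol = 1) else t(v) # T = 1 stays n x 1
  }
  rows <- as_row_mat(vapply(keys, function(k) unname(row_of[k]), integer(Ts[1])))
  daps <- as_row_mat(vapply(samples, `[[`, integer(Ts[1]), "daps"))
  structure(
    list(
      X = feat, rows = rows, daps = daps,
      labels = ifelse(vapply(samples, `[[`, character(1), "label") == "Ready", 2L, 1L),
      anchor_hd = vapply(samples, `[[`, integer(1), "anchor_hd"),
      plant_id = vapply(samples, `[[`, character(1), "plant_id"),
      n = length(samples), T = Ts[1], input_size = config$input_size
    ),
    class = "series_dataset"
  )
}

#' @export
print.series_dataset <- function(x, ...) {
  cat(sprintf("<series_dataset> %d series of length %d (%d Ready / %d Not-ready), %d unique images\n",
              x$n, x$T, sum(x$labels == 2L), sum(x$labels == 1L), nrow(x$X)))
  invisible(x)
}

# -- model --------------------------------------------------------------------

init_model <- function(config) {
  d <- config$input_size^2
  he <- config$encoder_hidden
  ed <- config$embedding_dim
  din <- config$T * ed
  hh <- config$head_hidden
  with_seed(derive_seed(config$seed, "init"), {
    params <- list(
      W1 = matrix(rnorm(d * he, 0, sqrt(2 / d)), d, he),
      b1 = numeric(he),
      W2 = matrix(rnorm(he * ed, 0, sqrt(2 / he)), he, ed),
      b2 = numeric(ed),
      U1 = matrix(rnorm(din * hh, 0, sqrt(2 / din)), din, hh),
      c1 = numeric(hh),
      U2 = matrix(rnorm(hh * 2, 0, sqrt(2 / hh)), hh, 2),
      c2 = numeric(2)
    )
  })
  structure(list(config = config, params = params), class = "ts_model")
}

#' @export
print.ts_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<ts_model> T = %d, %d parameters (%s backbone)\n",
              x$config$T, np, x$config$backbone))
  invisible(x)
}

pe_matrix <- function(daps_vec, dim) {
  uniq <- sort(unique(as.vector(daps_vec)))
  pem <- t(vapply(uniq, positional_encoding, numeric(dim), dim = dim))
  rownames(pem) <- as.character(uniq)
  pem
}

# Forward pass for a set of series. Returns scores and, if keep = TRUE, the
# intermediates needed for backpropagation.
forward_pass <- function(params, config, X, rows, daps, keep = FALSE) {
  B <- nrow(rows)
  Tn <- ncol(rows)
  ed <- config$embedding_dim
  Xb <- X[as.vector(t(rows)), , drop = FALSE]          # (B*T) x d, series-major
  E1pre <- sweep(Xb %*% params$W1, 2, params$b1, "+")
  E1 <- pmax(E1pre, 0)
  TPE <- sweep(E1 %*% params$W2, 2, params$b2, "+")
  pem <- pe_matrix(daps, ed)
  TPE <- TPE + pem[as.character(as.vector(t(daps))), , drop = FALSE]
  Z <- matrix(as.vector(t(TPE)), nrow = B, byrow = TRUE) # B x (T*ed)
  Hpre <- sweep(Z %*% params$U1, 2, params$c1, "+")
  H <- pmax(Hpre, 0)
  S <- sweep(H %*% params$U2, 2, params$c2, "+")
  out <- list(scores = S)
  if (keep) {
    out <- c(out, list(Xb = Xb, E1 = E1, Z = Z, H = H, B = B, Tn = Tn))
  }
  out
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

backward_pass <- function(params, fwd, labels) {
  B <- fwd$B
  P <- softmax_rows(fwd$scores)
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), labels)] <- 1
  dS <- (P - Y) / B
  dU2 <- crossprod(fwd$H, dS)
  dc2 <- colSums(dS)
  dH <- dS %*% t(params$U2)
  dHpre <- dH * (fwd$H > 0)
  dU1 <- crossprod(fwd$Z, dHpre)
  dc1 <- colSums(dHpre)
  dZ <- dHpre %*% t(params$U1)
  dTPE <- matrix(as.vector(t(dZ)), nrow = B * fwd$Tn, byrow = TRUE)
  dW2 <- crossprod(fwd$E1, dTPE)
  db2 <- colSums(dTPE)
  dE1 <- (dTPE %*% t(params$W2)) * (fwd$E1 > 0)
  dW1 <- crossprod(fwd$Xb, dE1)
  db1 <- colSums(dE1)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), labels)], 1e-12)))
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    U1 = dU1, c1 = dc1, U2 = dU2, c2 = dc2),
       loss = loss)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, alpha,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] + alpha * params[[nm]] # L2 weight decay
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Encode a single image at a given acquisition day
#'
#' Runs the shared encoder on one image and adds (optionally) the positional
#' encoding of its acquisition day, returning the time point embedding.
#'
#' @param model A trained or freshly initialised `ts_model`.
#' @param image Image array (h x w x 3 or matrix), or an already
#'   preprocessed feature vector of length `input_size^2`.
#' @param dap Day after planting of the acquisition.
#' @param include_positional Add the positional encoding of `dap`?
#' @return Numeric time point embedding of length `embedding_dim`.
#' @export
encode_time_point <- function(model, image, dap, include_positional = TRUE) {
  cfg <- model$config
  x <- if (is.null(dim(image))) {
    if (length(image) != cfg$input_size^2) {
      abort(sprintf("Feature vector length %d does not match input_size^2 = %d.",
                    length(image), cfg$input_size^2))
    }
    image
  } else {
    preprocess_image(image, character(0), cfg$input_size)
  }
  e1 <- pmax(as.vector(x %*% model$params$W1) + model$params$b1, 0)
  tpe <- as.vector(e1 %*% model$params$W2) + model$params$b2
  if (include_positional) tpe <- tpe + positional_encoding(dap, cfg$embedding_dim)
  tpe
}

#' Class scores for series in a dataset
#'
#' Deterministic evaluation-mode forward pass.
#'
#' @param model A `ts_model`.
#' @param dataset A [series_dataset()] with the same `T` as the model.
#' @param indices Optional subset of series indices.
#' @return Matrix with columns `not_ready`, `ready` (unnormalised scores).
#' @export
classify_series <- function(model, dataset, indices = NULL) {
  if (dataset$T != model$config$T) {
    abort(sprintf("Series length %d does not match model T = %d.",
                  dataset$T, model$config$T))
  }
  idx <- indices %||% seq_len(dataset$n)
  fwd <- forward_pass(model$params, model$config, dataset$X,
                      dataset$rows[idx, , drop = FALSE],
                      dataset$daps[idx, , drop = FALSE])
  colnames(fwd$scores) <- c("not_ready", "ready")
  fwd$scores
}

#' Predicted labels and Ready probabilities
#'
#' @inheritParams classify_series
#' @return A tibble with `plant_id`, `anchor_hd`, `label` (truth),
#'   `predicted` and `prob_ready`.
#' @export
predict_readiness <- function(model, dataset) {
  S <- classify_series(model, dataset)
  P <- softmax_rows(S)
  tibble(
    plant_id = dataset$plant_id,
    anchor_hd = dataset$anchor_hd,
    label = c("Not-ready", "Ready")[dataset$labels],
    predicted = c("Not-ready", "Ready")[max.col(S, ties.method = "first")],
    prob_ready = P[, 2]
  )
}

eval_oaacc <- function(model, dataset) {
  S <- classify_series(model, dataset)
  mean(max.col(S, ties.method = "first") == dataset$labels)
}

#' Train the time-series classifier
#'
#' Adam with L2 weight decay `alpha`, step learning-rate schedule, batches
#' of whole series (the loss of a series is accumulated over all of its
#' images through the shared encoder before the step). Training runs at
#' least `min_epochs` epochs and stops once validation overall accuracy has
#' not improved by more than 1e-4 for `patience` epochs; the checkpoint with
#' the highest validation overall accuracy is returned. Fully deterministic
#' given the config seed.
#'
#' @param train_ds,val_ds Training and validation [series_dataset()]s built
#'   from disjoint plant sets.
#' @param config A [model_config()].
#' @return A list with `model` (best checkpoint), `history` (tibble of
#'   epoch, lr, train_loss, val_oaacc, val_bcacc) and `best_epoch`.
#' @export
train_model <- function(train_ds, val_ds, config) {
  if (!train_ds$n || !val_ds$n) abort("Training and validation sets must be non-empty.")
  model <- init_model(config)
  params <- model$params
  state <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  n <- train_ds$n
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$scheduler_gamma^((epoch - 1) %/% config$scheduler_step)
    ord <- with_seed(derive_seed(config$seed, paste0("epoch_", epoch)), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1, n)]
      fwd <- forward_pass(params, config, train_ds$X,
                          train_ds$rows[bidx, , drop = FALSE],
                          train_ds$daps[bidx, , drop = FALSE], keep = TRUE)
      bwd <- backward_pass(params, fwd, train_ds$labels[bidx])
      upd <- adam_step(params, bwd$grads, state, lr, config$alpha)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, bwd$loss)
    }
    model$params <- params
    val_S <- classify_series(model, val_ds)
    val_pred <- max.col(val_S, ties.method = "first")
    val_oa <- mean(val_pred == val_ds$labels)
    val_bc <- tryCatch(
      balanced_accuracy(confusion_from_predictions(val_ds$labels == 2L, val_pred == 2L)),
      error = function(e) NA_real_
    )
    hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                            train_loss = mean(losses),
                            val_oaacc = val_oa, val_bcacc = val_bc)
    if (val_oa > best$acc + 1e-4) {
      # a significant improvement resets the early-stopping clock
      best <- list(acc = val_oa, params = params, epoch = epoch)
    } else if (val_oa >= best$acc) {
      # ties go to the later, better-converged checkpoint
      best$params <- params
    }
    if (epoch >= config$min_epochs && (epoch - best$epoch) >= config$patience) break
  }
  model$params <- best$params
  list(model = model, history = dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))]),
       best_epoch = best$epoch)
}

#' Grid search over weight decay and head scaling factor
#'
#' Trains one model per (alpha, lambda) combination and returns the
#' configuration with the highest validation overall accuracy. Ties are
#' broken deterministically toward the smaller lambda, then the smaller
#' alpha.
#'
#' @param train_ds,val_ds Datasets as in [train_model()].
#' @param config Base [model_config()]; `alpha` and `lambda` are overridden.
#' @param alphas,lambdas Grids (defaults: the customary ranges 1e-3..1e-1
#'   and 2..4).
#' @return List with `best_config`, `best_fit` and a `results` tibble.
#' @export
tune_hyperparameters <- function(train_ds, val_ds, config,
                                 alphas = c(1e-3, 1e-2, 1e-1),
                                 lambdas = 2:4) {
  if (!length(alphas) || !length(lambdas)) abort("Hyperparameter grid is empty.")
  grid <- expand.grid(alpha = sort(alphas), lambda = sort(lambdas))
  grid <- grid[order(grid$lambda, grid$alpha), , drop = FALSE]
  best <- NULL
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- model_config(
      T = config$T, embedding_dim = config$embedding_dim,
      lambda = grid$lambda[i], alpha = grid$alpha[i],
      learning_rate = config$learning_rate, batch_size = config$batch_size,
      scheduler_step = config$scheduler_step,
      scheduler_gamma = config$scheduler_gamma,
      min_epochs = config$min_epochs, patience = config$patience,
      max_epochs = config$max_epochs, backbone = config$backbone,
      input_size = config$input_size, encoder_hidden = config$encoder_hidden,
      seed = config$seed
    )
    fit <- train_model(train_ds, val_ds, cfg)
    acc <- eval_oaacc(fit$model, val_ds)
    rows[[i]] <- tibble(alpha = grid$alpha[i], lambda = grid$lambda[i],
                        val_oaacc = acc, best_epoch = fit$best_epoch)
    if (is.null(best) || acc > best$acc) {
      best <- list(acc = acc, config = cfg, fit = fit)
    }
  }
  list(best_config = best$config, best_fit = best$fit,
       results = dplyr::bind_rows(rows))
}

#' Time-series embeddings (TSEs) for a dataset
#'
#' Concatenated per-image embeddings (encoder output plus positional
#' encoding) for each series; the representation on which grouped Shapley
#' attribution operates.
#'
#' @inheritParams classify_series
#' @return Matrix of dimension `n x (T * embedding_dim)`.
#' @export
series_embeddings <- function(model, dataset, indices = NULL) {
  idx <- indices %||% seq_len(dataset$n)
  cfg <- model$config
  params <- model$params
  rows <- dataset$rows[idx, , drop = FALSE]
  daps <- dataset$daps[idx, , drop = FALSE]
  Xb <- dataset$X[as.vector(t(rows)), , drop = FALSE]
  E1 <- pmax(sweep(Xb %*% params$W1, 2, params$b1, "+"), 0)
  TPE <- sweep(E1 %*% params$W2, 2, params$b2, "+")
  pem <- pe_matrix(daps, cfg$embedding_dim)
  TPE <- TPE + pem[as.character(as.vector(t(daps))), , drop = FALSE]
  matrix(as.vector(t(TPE)), nrow = length(idx), byrow = TRUE)
}

#' Value function of the classification head over TSEs
#'
#' Returns a closure mapping a matrix of time-series embeddings to the
#' model's output for the Ready class, either as softmax probability or as
#' the score margin (logit).
#'
#' @param model A `ts_model`.
#' @param output `"prob"` (default) or `"logit"`.
#' @param class `"ready"` (default) or `"not_ready"`.
#' @return `function(Z)` returning a numeric vector, one value per row.
#' @export
head_value_fun <- function(model, output = c("prob", "logit"),
                           class = c("ready", "not_ready")) {
  output <- match.arg(output)
  class <- match.arg(class)
  params <- model$params
  col <- if (class == "ready") 2L else 1L
  function(Z) {
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
    H <- pmax(sweep(Z %*% params$U1, 2, params$c1, "+"), 0)
    S <- sweep(H %*% params$U2, 2, params$c2, "+")
    if (output == "prob") softmax_rows(S)[, col] else S[, col] - S[, 3L - col]
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file with a JSON sidecar
#' (`<path>.json`) holding the configuration.
#'
#' @param model A `ts_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  write_json_stable(model$config[setdiff(names(model$config), character(0))],
                    paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
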