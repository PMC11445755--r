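# Iterative acquisition-day selection:
# attribute -> exclude the non-fixed day with the lowest mean absolute
# grouped Shapley value -> rebuild series -> retrain from scratch -> repeat.

config_with_T <- function(config, T) {
  model_config(
    T = T, embedding_dim = config$embedding_dim, lambda = config$lambda,
    alpha = config$alpha, learning_rate = config$learning_rate,
    batch_size = config$batch_size, scheduler_step = config$scheduler_step,
    scheduler_gamma = config$scheduler_gamma, min_epochs = config$min_epochs,
    patience = config$patience, max_epochs = config$max_epochs,
    backbone = config$backbone, input_size = config$input_size,
    encoder_hidden = config$encoder_hidden, seed = config$seed
  )
}

#' Configuration of the selection loop
#'
#' @param model_config Base [model_config()] used for every retraining;
#'   its `T` is adjusted per step.
#' @param fixed_daps Acquisition days never eligible for exclusion. Default:
#'   the first three and last four days of the grid (the last four are the
#'   anchoring basic-image days, which every series must keep).
#' @param initial_T Starting series length; default is the largest length
#'   feasible for every harvest-day anchor on the grid (8 on the default
#'   11-day grid, limited by the first harvest day's history).
#' @param min_T Stop once series are this short (default 1: run until no
#'   excludable day remains).
#' @param max_iterations Cap on exclusion steps.
#' @param shap_mode `"exact"` or `"sampled"` attribution.
#' @param n_imputations,n_coalitions Attribution settings, see
#'   [compute_group_shap()].
#' @param val_frac Fraction of plants held out for validation; attribution
#'   and accuracies are computed on this split.
#' @param seed Seed for the plant split and per-step attribution streams.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(model_config,
                             fixed_daps = NULL,
                             initial_T = NULL,
                             min_T = 1L,
                             max_iterations = Inf,
                             shap_mode = c("exact", "sampled"),
                             n_imputations = 10L,
                             n_coalitions = NULL,
                             val_frac = 0.25,
                             seed = 0L) {
  shap_mode <- match.arg(shap_mode)
  structure(
    list(model_config = model_config, fixed_daps = fixed_daps,
         initial_T = initial_T, min_T = as.integer(min_T),
         max_iterations = max_iterations, shap_mode = shap_mode,
         n_imputations = as.integer(n_imputations),
         n_coalitions = n_coalitions, val_frac = val_frac,
         seed = as.integer(seed)),
    class = "selection_config"
  )
}

# Drop one acquisition day from every series of an in-memory dataset.
dataset_drop_dap <- function(ds, dap) {
  keep <- ds$daps != dap
  if (any(rowSums(!keep) != 1L)) {
    abort(sprintf("DAP %d is not present exactly once in every series.", dap))
  }
  nT <- ds$T - 1L
  ds$rows <- matrix(t(ds$rows)[t(keep)], ncol = nT, byrow = TRUE)
  ds$daps <- matrix(t(ds$daps)[t(keep)], ncol = nT, byrow = TRUE)
  ds$T <- nT
  ds
}

val_accuracies <- function(model, ds) {
  S <- classify_series(model, ds)
  pred <- max.col(S, ties.method = "first") == 2L
  truth <- ds$labels == 2L
  cc <- confusion_from_predictions(truth, pred)
  list(
    oaacc = overall_accuracy(cc),
    bcacc = tryCatch(balanced_accuracy(cc), error = function(e) NA_real_)
  )
}

safe_stage_string <- function(dap) {
  codes <- vapply(1:4, function(hd) {
    tryCatch(stage_lookup(dap, hd), error = function(e) "-")
  }, character(1))
  paste(codes, collapse = "/")
}

#' Run the iterative acquisition-day selection loop
#'
#' Starting from the longest feasible initial time series, repeatedly:
#' train the classifier from scratch, attribute the Ready output of the
#' validation series to individual acquisition days with grouped Shapley
#' values, combine the absolute contributions across harvest days, and
#' exclude the eligible day with the lowest mean absolute contribution
#' (ties broken toward the earlier day). A day is eligible if it is not
#' fixed and appears in the current series of every harvest day, so whole
#' flights can be dropped field-wide. The loop stops at `min_T`, at
#' `max_iterations`, or when no eligible day remains.
#'
#' @param manifest Observation manifest (see [read_manifest()]).
#' @param config A [selection_config()].
#' @param root Directory for image paths; defaults to the manifest's.
#' @return A `selection_trace`: a tibble with one row per exclusion step
#'   (`step`, `excluded_dap`, `mean_abs_phi`, `oaacc`, `bcacc`,
#'   `remaining_daps`, `bbch_stages`), with attributes `initial_T`,
#'   `initial_oaacc`, `initial_bcacc`, `fixed_daps`, `final_model`.
#' @export
run_selection <- function(manifest, config, root = NULL) {
  stopifnot(inherits(config, "selection_config"))
  root <- root %||% attr(manifest, "root") %||% "."
  grid <- sort(unique(manifest$dap))
  n_days <- length(grid)
  fixed <- config$fixed_daps %||% grid[c(1:3, (n_days - 3L):n_days)]
  if (!all(tail(grid, 4L) %in% fixed)) {
    abort("`fixed_daps` must contain the four anchoring basic-image days.")
  }
  T0 <- config$initial_T %||% (n_days - 3L)

  splits <- split_plants(manifest, val_frac = config$val_frac, seed = config$seed)
  tr_samples <- build_series(splits$train, T0)
  val_samples <- build_series(splits$val, T0)
  mcfg <- config_with_T(config$model_config, T0)
  ds_tr <- series_dataset(tr_samples, mcfg, root)
  ds_val <- series_dataset(val_samples, mcfg, root)

  fit <- train_model(ds_tr, ds_val, mcfg)
  acc0 <- val_accuracies(fit$model, ds_val)

  trace_rows <- list()
  step <- 0L
  while (ds_tr$T > config$min_T && step < config$max_iterations) {
    shap <- compute_group_shap(
      fit$model, ds_val, ds_tr, mode = config$shap_mode,
      n_imputations = config$n_imputations,
      n_coalitions = config$n_coalitions,
      seed = derive_seed(config$seed, paste0("shap_step_", step))
    )
    summ <- summarize_contributions(shap)
    # eligible: non-fixed and present in the current window of every anchor
    windows <- lapply(sort(unique(c(ds_tr$anchor_hd, ds_val$anchor_hd))), function(h) {
      i <- which(ds_tr$anchor_hd == h)[1]
      if (is.na(i)) {
        j <- which(ds_val$anchor_hd == h)[1]
        ds_val$daps[j, ]
      } else {
        ds_tr$daps[i, ]
      }
    })
    in_all <- Reduce(intersect, windows)
    eligible <- setdiff(intersect(in_all, summ$by_dap$dap), fixed)
    if (!length(eligible)) break
    cand <- summ$by_dap[summ$by_dap$dap %in% eligible, ]
    cand <- cand[order(cand$dap), ]
    excl <- cand$dap[which.min(cand$mean_abs_phi)]

    ds_tr <- dataset_drop_dap(ds_tr, excl)
    ds_val <- dataset_drop_dap(ds_val, excl)
    step <- step + 1L
    mcfg <- config_with_T(config$model_config, ds_tr$T)
    fit <- train_model(ds_tr, ds_val, mcfg)
    acc <- val_accuracies(fit$model, ds_val)
    trace_rows[[step]] <- tibble(
      step = step,
      excluded_dap = excl,
      mean_abs_phi = cand$mean_abs_phi[cand$dap == excl],
      T = ds_tr$T,
      oaacc = acc$oaacc,
      bcacc = acc$bcacc,
      remaining_daps = paste(sort(unique(as.vector(ds_tr$daps))), collapse = " "),
      bbch_stages = safe_stage_string(excl)
    )
  }
  trace <- if (length(trace_rows)) dplyr::bind_rows(trace_rows) else {
    tibble(step = integer(0), excluded_dap = integer(0),
           mean_abs_phi = numeric(0), T = integer(0), oaacc = numeric(0),
           bcacc = numeric(0), remaining_daps = character(0),
           bbch_stages = character(0))
  }
  structure(trace,
            class = c("selection_trace", class(trace)),
            initial_T = T0, initial_oaacc = acc0$oaacc,
            initial_bcacc = acc0$bcacc, fixed_daps = fixed,
            final_model = fit$model)
}

#' Accuracy of initial time series across lengths
#'
#' Trains one model per series length `T` (the `T = 1` model is the
#' single-time-point baseline) and reports validation accuracies.
#'
#' @param manifest Observation manifest.
#' @param Ts Series lengths to evaluate; default `1..initial_T`.
#' @param config Base [model_config()].
#' @param val_frac,seed Plant split settings (match the selection run for
#'   comparable curves).
#' @param root Image directory.
#' @return Tibble with columns `T`, `oaacc`, `bcacc`, `best_epoch`.
#' @export
run_its_curve <- function(manifest, Ts = NULL, config, val_frac = 0.25,
                          seed = 0L, root = NULL) {
  root <- root %||% attr(manifest, "root") %||% "."
  grid <- sort(unique(manifest$dap))
  Ts <- Ts %||% seq_len(length(grid) - 3L)
  splits <- split_plants(manifest, val_frac = val_frac, seed = seed)
  rows <- lapply(Ts, function(T) {
    mcfg <- config_with_T(config, T)
    ds_tr <- series_dataset(build_series(splits$train, T), mcfg, root)
    ds_val <- series_dataset(build_series(splits$val, T), mcfg, root)
    fit <- train_model(ds_tr, ds_val, mcfg)
    acc <- val_accuracies(fit$model, ds_val)
    tibble(T = T, oaacc = acc$oaacc, bcacc = acc$bcacc,
           best_epoch = fit$best_epoch)
  })
  dplyr::bind_rows(rows)
}

#' Combined accuracy-versus-length table
#'
#' Opposes the single-time-point baseline (`T = 1`), the initial time
#' series across lengths, and the selective time series produced by
#' [run_selection()], in one table ready for plotting.
#'
#' @param its Tibble from [run_its_curve()].
#' @param trace A `selection_trace` from [run_selection()].
#' @return Tibble with columns `family` (`baseline` / `iTS` / `sTS`), `T`,
#'   `oaacc`, `bcacc`.
#' @export
accuracy_curve <- function(its, trace) {
  if (is.null(its) || !nrow(its)) abort("Missing initial time-series runs.")
  baseline <- its[its$T == 1L, , drop = FALSE]
  rows <- list()
  if (nrow(baseline)) {
    rows$baseline <- tibble(family = "baseline", T = baseline$T,
                            oaacc = baseline$oaacc, bcacc = baseline$bcacc)
  }
  rows$its <- tibble(family = "iTS", T = its$T, oaacc = its$oaacc,
                     bcacc = its$bcacc)
  sts <- tibble(
    family = "sTS",
    T = c(attr(trace, "initial_T"), trace$T),
    oaacc = c(attr(trace, "initial_oaacc"), trace$oaacc),
    bcacc = c(attr(trace, "initial_bcacc"), trace$bcacc)
  )
  rows$sts <- sts
  dplyr::bind_rows(rows)
}
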