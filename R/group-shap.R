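# Grouped Shapley attribution over time-series embeddings.
#
# Players are whole time points: each group is the 32-feature block of one
# time point embedding inside the concatenated series embedding. Absent
# groups in a coalition are imputed with the corresponding blocks of
# training-set embeddings and the value function averaged over the
# imputations. Exact mode enumerates all 2^M coalitions; sampled mode is a
# Shapley-kernel weighted least-squares estimate with the full and empty
# coalitions pinned.

#' Group structure of a time-series embedding
#'
#' @param M Number of groups (time points).
#' @param dim_per_group Features per group (the embedding dimension).
#' @return Object of class `group_spec` with fields `M`, `dim_per_group`,
#'   `assign` (feature -> group index) and `slices`.
#' @export
group_spec <- function(M, dim_per_group = 32L) {
  M <- as.integer(M)
  d <- as.integer(dim_per_group)
  if (M < 1L || d < 1L) abort("`M` and `dim_per_group` must be positive.")
  structure(
    list(M = M, dim_per_group = d,
         assign = rep(seq_len(M), each = d),
         slices = lapply(seq_len(M), function(t) ((t - 1L) * d + 1L):(t * d))),
    class = "group_spec"
  )
}

draw_imputation_idx <- function(n_background, n_imputations, seed) {
  if (n_background < 1L) abort("Background set must be non-empty.")
  if (n_imputations >= n_background) {
    seq_len(n_background) # exhaustive: every background example used once
  } else {
    with_seed(derive_seed(seed, "imputation"),
              sample.int(n_background, n_imputations))
  }
}

# Mean value over imputations for each coalition row of `masks` (0/1, n x M).
# Chunked so that the expanded matrix never exceeds ~2^12 rows at a time.
coalition_values <- function(value_fun, x, background, spec, imput_idx, masks) {
  D <- length(x)
  n <- nrow(masks)
  v <- numeric(n)
  chunk <- 4096L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    cm <- masks[lo:hi, spec$assign, drop = FALSE]
    xr <- matrix(x, hi - lo + 1L, D, byrow = TRUE)
    acc <- numeric(hi - lo + 1L)
    for (i in imput_idx) {
      br <- matrix(background[i, ], hi - lo + 1L, D, byrow = TRUE)
      acc <- acc + value_fun(cm * xr + (1 - cm) * br)
    }
    v[lo:hi] <- acc / length(imput_idx)
  }
  v
}

coalition_masks <- function(M) {
  codes <- 0:(2^M - 1)
  vapply(seq_len(M), function(t) as.numeric(bitwAnd(codes, 2^(t - 1)) > 0),
         numeric(length(codes)))
}

new_group_shap_result <- function(base_value, phi, model_output, method,
                                  daps = NULL, anchor_hd = NA_integer_,
                                  plant_id = NA_character_) {
  if (!is.null(daps)) names(phi) <- daps
  structure(
    list(base_value = base_value, phi = phi, model_output = model_output,
         method = method, daps = daps, anchor_hd = anchor_hd,
         plant_id = plant_id),
    class = "group_shap_result"
  )
}

#' @export
print.group_shap_result <- function(x, ...) {
  cat(sprintf("<group_shap_result> (%s) base %.4f, output %.4f, local error %.2e\n",
              x$method, x$base_value, x$model_output,
              abs(x$base_value + sum(x$phi) - x$model_output)))
  print(round(x$phi, 4))
  invisible(x)
}

#' Exact grouped Shapley values by coalition enumeration
#'
#' Enumerates all `2^M` coalitions. For each coalition the absent groups are
#' filled with the corresponding blocks of background (training-set)
#' embeddings and the value function averaged over the imputation draws;
#' one shared imputation draw per call is used for every coalition, so the
#' coalition value depends only on the coalition. Shapley values are the
#' classical weighted sums of coalition differences
#' `phi_t = sum_{S not containing t} |S|! (M-|S|-1)! / M! (v(S+t) - v(S))`.
#' Local accuracy `base + sum(phi) = output` holds to machine precision.
#'
#' @param value_fun Function mapping a matrix of embeddings (one per row)
#'   to a numeric output per row, e.g. [head_value_fun()].
#' @param x The embedding to explain (numeric vector).
#' @param background Matrix of background embeddings (one per row).
#' @param spec A [group_spec()]; defaults to 32-feature groups.
#' @param n_imputations Background draws per coalition; if at least the
#'   background size, the whole background is used (exhaustive).
#' @param seed Seed for the imputation draw.
#' @param daps,anchor_hd,plant_id Optional metadata carried into the result.
#' @return A `group_shap_result` with `base_value` (mean output over the
#'   imputation set), `phi` (one value per group) and `model_output`.
#' @export
group_shap_exact <- function(value_fun, x, background, spec = NULL,
                             n_imputations = 10L, seed = 0L, daps = NULL,
                             anchor_hd = NA_integer_, plant_id = NA_character_) {
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  spec <- spec %||% group_spec(length(x) %/% 32L, 32L)
  M <- spec$M
  if (length(x) != M * spec$dim_per_group) {
    abort("Length of `x` does not match the group specification.")
  }
  if (ncol(background) != length(x)) abort("Background width does not match `x`.")
  if (M > 15L) abort("Exact enumeration is limited to M <= 15 groups; use group_shap_sampled().")
  imput_idx <- draw_imputation_idx(nrow(background), n_imputations, seed)
  masks <- coalition_masks(M)
  v <- coalition_values(value_fun, x, background, spec, imput_idx, masks)
  codes <- 0:(2^M - 1)
  pc <- as.integer(rowSums(masks))
  w <- exp(lfactorial(0:(M - 1)) + lfactorial(M - 1 - 0:(M - 1)) - lfactorial(M))
  phi <- numeric(M)
  for (t in seq_len(M)) {
    bt <- 2^(t - 1)
    without <- codes[bitwAnd(codes, bt) == 0L]
    phi[t] <- sum(w[pc[without + 1L] + 1L] * (v[without + bt + 1L] - v[without + 1L]))
  }
  new_group_shap_result(
    base_value = v[1L], phi = phi,
    model_output = as.numeric(value_fun(matrix(x, nrow = 1))),
    method = "exact", daps = daps, anchor_hd = anchor_hd, plant_id = plant_id
  )
}

shapley_kernel <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

# Budgeted coalition sampling: enumerate complete size strata from the
# outside in (sizes 1 and M-1 carry the largest kernel weight) while the
# budget allows, then sample the remainder from the leftover strata in
# proportion to their kernel mass. Returns masks and regression weights.
sample_coalitions <- function(M, n_coalitions, seed) {
  sizes <- seq_len(M - 1L)
  stratum_mass <- (M - 1) / (sizes * (M - sizes)) # choose(M,s) * kernel(M, s)
  stratum_n <- choose(M, sizes)
  order_pairs <- unique(as.vector(rbind(sizes, rev(sizes))))
  masks <- NULL
  weights <- numeric(0)
  budget <- n_coalitions
  enumerated <- logical(M - 1L)
  for (s in order_pairs) {
    if (enumerated[s]) next
    if (stratum_n[s] <= budget) {
      combs <- utils::combn(M, s)
      m <- matrix(0, ncol(combs), M)
      m[cbind(rep(seq_len(ncol(combs)), each = s), as.vector(combs))] <- 1
      masks <- rbind(masks, m)
      weights <- c(weights, rep(shapley_kernel(M, s), ncol(combs)))
      budget <- budget - stratum_n[s]
      enumerated[s] <- TRUE
    }
  }
  left <- which(!enumerated)
  if (length(left) && budget > 0L) {
    probs <- stratum_mass[left] / sum(stratum_mass[left])
    drawn <- with_seed(derive_seed(seed, "coalitions"), {
      ss <- sample(left, budget, replace = TRUE, prob = probs)
      lapply(ss, function(s) sample.int(M, s))
    })
    m <- matrix(0, length(drawn), M)
    for (i in seq_along(drawn)) m[i, drawn[[i]]] <- 1
    counts <- table(factor(lengths(drawn), levels = left))
    wmap <- stratum_mass[left] / pmax(1, as.numeric(counts))
    names(wmap) <- left
    masks <- rbind(masks, m)
    weights <- c(weights, wmap[as.character(lengths(drawn))])
  }
  list(masks = masks, weights = unname(weights))
}

#' Sampled grouped Shapley values (kernel-weighted least squares)
#'
#' Estimates the grouped Shapley values from a budget of coalitions with
#' Shapley-kernel weights `(M-1) / (choose(M,|S|) |S| (M-|S|))`; the full
#' and empty coalitions are pinned exactly (the infinite-weight limit), so
#' local accuracy holds by construction. With the complete coalition set
#' the estimate equals the exact Shapley values. The imputation draw is
#' shared with [group_shap_exact()] for the same seed.
#'
#' @inheritParams group_shap_exact
#' @param n_coalitions Number of coalitions (at least `M + 2`); budgets at
#'   or above `2^M - 2` enumerate every non-trivial coalition.
#' @return A `group_shap_result`.
#' @export
group_shap_sampled <- function(value_fun, x, background, spec = NULL,
                               n_coalitions = NULL, n_imputations = 10L,
                               seed = 0L, daps = NULL,
                               anchor_hd = NA_integer_, plant_id = NA_character_) {
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  spec <- spec %||% group_spec(length(x) %/% 32L, 32L)
  M <- spec$M
  n_coalitions <- as.integer(n_coalitions %||% min(2^M - 2, max(2L * M + 4L, 256L)))
  if (n_coalitions < M + 2L) abort("`n_coalitions` must be at least M + 2.")
  imput_idx <- draw_imputation_idx(nrow(background), n_imputations, seed)

  if (n_coalitions >= 2^M - 2) {
    all_masks <- coalition_masks(M)
    keep <- rowSums(all_masks) > 0 & rowSums(all_masks) < M
    masks <- all_masks[keep, , drop = FALSE]
    weights <- shapley_kernel(M, rowSums(masks))
  } else {
    sc <- sample_coalitions(M, n_coalitions, seed)
    masks <- sc$masks
    weights <- sc$weights
  }

  v <- coalition_values(value_fun, x, background, spec, imput_idx, masks)
  v_empty <- coalition_values(value_fun, x, background, spec, imput_idx,
                              matrix(0, 1, M))
  v_full <- as.numeric(value_fun(matrix(x, nrow = 1)))

  # Constrained WLS: sum(phi) = v_full - v_empty, eliminate phi_M.
  y <- v - v_empty
  total <- v_full - v_empty
  A <- masks[, -M, drop = FALSE] - masks[, M]
  y2 <- y - masks[, M] * total
  XtWX <- crossprod(A, A * weights)
  phi_rest <- tryCatch(
    solve(XtWX, crossprod(A, y2 * weights)),
    error = function(e) abort(paste0(
      "Degenerate coalition design (singular weighted system): ", conditionMessage(e)
    ))
  )
  phi <- c(as.vector(phi_rest), total - sum(phi_rest))
  new_group_shap_result(
    base_value = v_empty, phi = phi, model_output = v_full,
    method = "sampled", daps = daps, anchor_hd = anchor_hd, plant_id = plant_id
  )
}

#' Grouped Shapley attribution for every series in a dataset
#'
#' Computes the time-series embeddings of the dataset under the model,
#' takes the training-split embeddings as background, and attributes the
#' Ready output of the classification head to the individual time points of
#' each series.
#'
#' @param model A trained `ts_model`.
#' @param dataset [series_dataset()] of series to explain.
#' @param background [series_dataset()] (or embedding matrix) providing the
#'   imputation background, normally the training split. When a dataset is
#'   given, each sample is imputed only from background series anchored at
#'   the same harvest day: series of different harvest days cover different
#'   acquisition-day windows, so only same-anchor series place the same
#'   acquisition day (and its positional encoding) at the same position.
#' @param mode `"exact"` (coalition enumeration) or `"sampled"`.
#' @param output Head output attributed: `"prob"` (softmax probability of
#'   Ready, default) or `"logit"`.
#' @param n_imputations Background draws per coalition.
#' @param n_coalitions Sampled mode budget (see [group_shap_sampled()]).
#' @param seed Master seed; each sample gets a derived substream.
#' @return A list of `group_shap_result` (class `group_shap_results`).
#' @export
compute_group_shap <- function(model, dataset, background,
                               mode = c("exact", "sampled"),
                               output = c("prob", "logit"),
                               n_imputations = 10L, n_coalitions = NULL,
                               seed = 0L) {
  mode <- match.arg(mode)
  output <- match.arg(output)
  Z <- series_embeddings(model, dataset)
  if (inherits(background, "series_dataset")) {
    bg_all <- series_embeddings(model, background)
    bg_anchor <- background$anchor_hd
  } else {
    bg_all <- background
    bg_anchor <- NULL
  }
  vf <- head_value_fun(model, output = output)
  spec <- group_spec(dataset$T, model$config$embedding_dim)
  results <- vector("list", dataset$n)
  for (i in seq_len(dataset$n)) {
    sub_seed <- derive_seed(seed, paste0("shap_", dataset$plant_id[i], "_",
                                         dataset$anchor_hd[i]))
    bg <- if (!is.null(bg_anchor) && any(bg_anchor == dataset$anchor_hd[i])) {
      bg_all[bg_anchor == dataset$anchor_hd[i], , drop = FALSE]
    } else {
      bg_all
    }
    results[[i]] <- if (mode == "exact") {
      group_shap_exact(vf, Z[i, ], bg, spec, n_imputations, sub_seed,
                       daps = dataset$daps[i, ], anchor_hd = dataset$anchor_hd[i],
                       plant_id = dataset$plant_id[i])
    } else {
      group_shap_sampled(vf, Z[i, ], bg, spec, n_coalitions, n_imputations,
                         sub_seed, daps = dataset$daps[i, ],
                         anchor_hd = dataset$anchor_hd[i],
                         plant_id = dataset$plant_id[i])
    }
  }
  structure(results, class = "group_shap_results")
}

#' Per-time-point contribution summary
#'
#' Aggregates absolute Shapley values by acquisition day, combined across
#' harvest days (the field-wide view used for exclusion decisions) and per
#' harvest day (quantiles for violin-style distribution plots), and
#' identifies the day with the lowest combined mean absolute contribution.
#'
#' @param results A `group_shap_results` list (or list of
#'   `group_shap_result`).
#' @return A list of class `group_shap_summary` with `by_dap` (tibble:
#'   `dap`, `n`, `mean_abs_phi`), `per_hd` (tibble of quantiles per
#'   harvest day and day, including the combined `"all"` rows) and
#'   `argmin_dap`.
#' @export
summarize_contributions <- function(results) {
  if (!length(results)) abort("No attribution results to summarise.")
  Ms <- vapply(results, function(r) length(r$phi), integer(1))
  if (length(unique(Ms)) != 1L) abort("Inconsistent group counts across results.")
  long <- dplyr::bind_rows(lapply(results, function(r) {
    tibble(
      dap = if (!is.null(r$daps)) as.integer(r$daps) else seq_along(r$phi),
      hd = as.character(r$anchor_hd %||% NA_integer_),
      phi = as.numeric(r$phi)
    )
  }))
  by_dap <- long |>
    dplyr::group_by(.data$dap) |>
    dplyr::summarise(n = dplyr::n(), mean_abs_phi = mean(abs(.data$phi)),
                     .groups = "drop") |>
    dplyr::arrange(.data$dap)
  qtl <- function(df) {
    df |>
      dplyr::group_by(.data$hd, .data$dap) |>
      dplyr::summarise(
        n = dplyr::n(), mean_phi = mean(.data$phi),
        mean_abs_phi = mean(abs(.data$phi)),
        q05 = quantile(.data$phi, 0.05, names = FALSE),
        q25 = quantile(.data$phi, 0.25, names = FALSE),
        q50 = quantile(.data$phi, 0.50, names = FALSE),
        q75 = quantile(.data$phi, 0.75, names = FALSE),
        q95 = quantile(.data$phi, 0.95, names = FALSE),
        .groups = "drop"
      )
  }
  per_hd <- dplyr::bind_rows(
    qtl(long),
    qtl(dplyr::mutate(long, hd = "all"))
  ) |>
    dplyr::arrange(.data$hd, .data$dap)
  argmin <- by_dap$dap[which.min(by_dap$mean_abs_phi)]
  structure(list(by_dap = by_dap, per_hd = per_hd, argmin_dap = argmin),
            class = "group_shap_summary")
}

#' @export
print.group_shap_summary <- function(x, ...) {
  cat("<group_shap_summary>\n")
  print(x$by_dap)
  cat("lowest combined mean |phi| at DAP", x$argmin_dap, "\n")
  invisible(x)
}

#' Write attribution results as JSON lines
#'
#' @param results A `group_shap_results` list.
#' @param path Output path.
#' @export
write_shap_results <- function(results, path) {
  lines <- vapply(results, function(r) {
    jsonlite::toJSON(list(
      plant_id = jsonlite::unbox(r$plant_id),
      anchor_hd = jsonlite::unbox(r$anchor_hd),
      base_value = jsonlite::unbox(r$base_value),
      model_output = jsonlite::unbox(r$model_output),
      daps = r$daps, phi = unname(r$phi)
    ), digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
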