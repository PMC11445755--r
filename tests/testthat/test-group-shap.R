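# The exact enumerator is checked against an independent
# permutation-enumeration oracle; the sampled estimator against the exact
# one. Imputation streams are shared through the seed so coalition values
# coincide across routes.

test_that("exact grouped Shapley matches the permutation-enumeration oracle", {
  for (M in c(3, 4, 5)) {
    d <- 4
    spec <- group_spec(M, d)
    vf <- random_head(M, d, seed = M)
    withr::with_seed(100 + M, {
      x <- rnorm(M * d)
      bg <- matrix(rnorm(7 * M * d), 7, M * d)
    })
    res <- group_shap_exact(vf, x, bg, spec, n_imputations = 5, seed = 3)
    rows <- shared_imputation(nrow(bg), 5, 3)
    oracle <- permutation_shapley(vf, x, bg, spec$slices, rows)
    expect_equal(res$phi, oracle, tolerance = 1e-6)
    expect_lt(abs(res$base_value + sum(res$phi) - res$model_output), 1e-6)
  }
})

test_that("additive value functions give the closed-form attribution", {
  # f(z) = sum_t g_t(z_t)  =>  phi_t = g_t(x) - mean_bg g_t(bg)
  M <- 4; d <- 3
  spec <- group_spec(M, d)
  withr::with_seed(8, {
    betas <- lapply(1:M, function(t) rnorm(d))
    x <- rnorm(M * d)
    bg <- matrix(rnorm(10 * M * d), 10, M * d)
  })
  vf <- function(Z) {
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
    out <- 0
    for (t in 1:M) out <- out + tanh(Z[, spec$slices[[t]], drop = FALSE] %*% betas[[t]])
    as.vector(out)
  }
  res <- group_shap_exact(vf, x, bg, spec, n_imputations = 10, seed = 0)
  g <- function(z, t) as.numeric(tanh(z[spec$slices[[t]]] %*% betas[[t]]))
  closed <- vapply(1:M, function(t) {
    g(x, t) - mean(apply(bg, 1, g, t = t))
  }, numeric(1))
  expect_equal(res$phi, closed, tolerance = 1e-10)
})

test_that("dummy and symmetry axioms hold in exact mode", {
  M <- 4; d <- 3
  spec <- group_spec(M, d)
  withr::with_seed(9, {
    beta <- rnorm(d)
    x <- rnorm(M * d)
    x[spec$slices[[2]]] <- x[spec$slices[[1]]] # identical content in groups 1, 2
    bg <- matrix(rnorm(8 * M * d), 8, M * d)
    bg[, spec$slices[[2]]] <- bg[, spec$slices[[1]]]
  })
  # head ignores group 3 entirely; groups 1 and 2 play symmetric roles
  vf <- function(Z) {
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
    a <- Z[, spec$slices[[1]], drop = FALSE] %*% beta
    b <- Z[, spec$slices[[2]], drop = FALSE] %*% beta
    d4 <- Z[, spec$slices[[4]], drop = FALSE] %*% beta
    as.vector(tanh(a) + tanh(b) + 0.5 * sin(d4))
  }
  res <- group_shap_exact(vf, x, bg, spec, n_imputations = 8, seed = 1)
  expect_equal(res$phi[3], 0, tolerance = 1e-12)   # dummy
  expect_equal(res$phi[1], res$phi[2], tolerance = 1e-6) # symmetry
})

test_that("sampled estimator with the full coalition set matches exact", {
  M <- 6; d <- 4
  spec <- group_spec(M, d)
  vf <- random_head(M, d, seed = 2)
  withr::with_seed(21, {
    x <- rnorm(M * d)
    bg <- matrix(rnorm(9 * M * d), 9, M * d)
  })
  ex <- group_shap_exact(vf, x, bg, spec, n_imputations = 5, seed = 4)
  sa <- group_shap_sampled(vf, x, bg, spec, n_coalitions = 2^M,
                           n_imputations = 5, seed = 4)
  expect_equal(sa$phi, ex$phi, tolerance = 1e-6)
  expect_equal(sa$base_value, ex$base_value, tolerance = 1e-12)
})

test_that("base value is the mean model output over the background", {
  M <- 3; d <- 2
  spec <- group_spec(M, d)
  vf <- random_head(M, d, seed = 5)
  withr::with_seed(30, {
    x <- rnorm(M * d)
    bg <- matrix(rnorm(12 * M * d), 12, M * d)
  })
  res <- group_shap_exact(vf, x, bg, spec, n_imputations = 12, seed = 0)
  expect_equal(res$base_value, mean(vf(bg)), tolerance = 1e-12)
})

test_that("sampled estimator converges with the coalition budget", {
  M <- 8; d <- 4
  spec <- group_spec(M, d)
  vf <- random_head(M, d, seed = 6)
  withr::with_seed(31, {
    x <- rnorm(M * d)
    bg <- matrix(rnorm(10 * M * d), 10, M * d)
  })
  ex <- group_shap_exact(vf, x, bg, spec, n_imputations = 10, seed = 7)
  budgets <- c(24, 64, 254)
  errs <- vapply(budgets, function(nc) {
    errs_seed <- vapply(1:5, function(s) {
      sa <- group_shap_sampled(vf, x, bg, spec, n_coalitions = nc,
                               n_imputations = 10, seed = 7 + 1000 * s)
      max(abs(sa$phi - ex$phi))
    }, numeric(1))
    mean(errs_seed)
  }, numeric(1))
  expect_true(errs[3] <= errs[1])
  expect_lt(errs[3], 0.05 * max(abs(ex$phi)) + 1e-9)
})

test_that("class complement: Not-ready attributions are the negated Ready ones", {
  field <- fixture_field(n_plants = 10, seed = 3)
  cfg <- fast_config(T = 3)
  ds <- series_dataset(build_series(field$manifest, 3), cfg, field$dir)
  model <- harvshap:::init_model(cfg)
  ready <- compute_group_shap(model, ds, ds, mode = "exact",
                              output = "prob", seed = 1)
  vf_nr <- head_value_fun(model, output = "prob", class = "not_ready")
  Z <- series_embeddings(model, ds)
  bg_anchor <- ds$anchor_hd
  for (i in c(1, 5)) {
    bg <- series_embeddings(model, ds)[bg_anchor == ds$anchor_hd[i], , drop = FALSE]
    sub_seed <- harvshap:::derive_seed(1, paste0("shap_", ds$plant_id[i], "_", ds$anchor_hd[i]))
    nr <- group_shap_exact(vf_nr, Z[i, ], bg, group_spec(3, 32),
                           n_imputations = 10, seed = sub_seed)
    expect_equal(nr$phi, -unname(ready[[i]]$phi), tolerance = 1e-10)
  }
})

test_that("errors on invalid inputs", {
  spec <- group_spec(16, 2)
  vf <- function(Z) rowSums(Z)
  expect_error(group_shap_exact(vf, rnorm(32), matrix(rnorm(64), 2), spec),
               "M <= 15")
  expect_error(group_shap_sampled(vf, rnorm(8), matrix(rnorm(16), 2),
                                  group_spec(4, 2), n_coalitions = 3),
               "at least M")
  expect_error(harvshap:::draw_imputation_idx(0, 5, 1), "non-empty")
})

test_that("contribution summaries aggregate by acquisition day", {
  mk <- function(phi, daps, hd) {
    harvshap:::new_group_shap_result(0, phi, sum(phi), "exact",
                                     daps = daps, anchor_hd = hd,
                                     plant_id = "p1")
  }
  res <- structure(list(
    mk(c(0, 0.5, -0.2), c(44, 50, 69), 1L),
    mk(c(0, -0.1, 0.4), c(44, 50, 71), 2L)
  ), class = "group_shap_results")
  summ <- summarize_contributions(res)
  expect_equal(summ$by_dap$mean_abs_phi[summ$by_dap$dap == 44], 0)
  expect_equal(summ$argmin_dap, 44)
  expect_equal(summ$by_dap$mean_abs_phi[summ$by_dap$dap == 50], 0.3)
  # single-sample summary equals that sample's absolute values
  one <- summarize_contributions(structure(list(res[[1]]), class = "group_shap_results"))
  expect_equal(one$by_dap$mean_abs_phi, abs(res[[1]]$phi)[order(res[[1]]$daps)],
               ignore_attr = TRUE)
  expect_error(summarize_contributions(list()), "No attribution")
  bad <- structure(list(mk(c(0, 1), c(44, 50), 1L), res[[1]]),
                   class = "group_shap_results")
  expect_error(summarize_contributions(bad), "Inconsistent")
})
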