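# Shared fixtures. Fields are rendered once per parameter signature and
# cached for the session; all tests work at desk scale (small fields,
# 32 px images, shortened epoch budgets).

.field_cache <- new.env(parent = emptyenv())

fixture_field <- function(n_plants = 24, seed = 1, informative_daps = NULL,
                          signal_free = FALSE, image_size = 32) {
  key <- paste(n_plants, seed, paste(informative_daps, collapse = "-"),
               signal_free, image_size, sep = "|")
  if (!is.null(.field_cache[[key]])) return(.field_cache[[key]])
  params <- growth_params(
    n_plants = n_plants, image_size = image_size,
    informative_daps = informative_daps %||% default_acquisition_daps(),
    signal_free = signal_free, seed = seed
  )
  dir <- file.path(tempdir(), paste0("field_", gsub("[^0-9a-zA-Z]", "_", key)))
  field <- simulate_field(params, dir)
  .field_cache[[key]] <- field
  field
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shortened training schedule for unit tests; the architecture and
# optimizer protocol are unchanged.
fast_config <- function(T, ...) {
  model_config(T = T, min_epochs = 20L, patience = 5L, max_epochs = 40L, ...)
}

# Mirror of the implementation's imputation draw, used to feed oracles the
# same background rows when a shared stream is required.
shared_imputation <- function(n_background, n_imputations, seed) {
  if (n_imputations >= n_background) seq_len(n_background)
  else withr::with_seed(harvshap:::derive_seed(seed, "imputation"),
                        sample.int(n_background, n_imputations))
}

# Independent permutation-enumeration Shapley oracle. Builds coalition
# values by explicit per-row imputation loops and averages marginal
# contributions over all M! orderings; shares only the value-function
# semantics (and imputation rows, passed in) with the implementation.
permutation_shapley <- function(value_fun, x, background, slices, imput_rows) {
  M <- length(slices)
  v_of <- function(S) {
    idx <- if (length(S)) unlist(slices[S]) else integer(0)
    vals <- vapply(imput_rows, function(i) {
      z <- background[i, ]
      z[idx] <- x[idx]
      as.numeric(value_fun(matrix(z, nrow = 1)))
    }, numeric(1))
    mean(vals)
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  # cache subset values by bitmask code
  v_cache <- new.env(parent = emptyenv())
  v_memo <- function(S) {
    code <- as.character(sum(2^(S - 1)))
    if (is.null(v_cache[[code]])) v_cache[[code]] <- v_of(S)
    v_cache[[code]]
  }
  phi <- numeric(M)
  perms <- all_perms(seq_len(M))
  for (p in perms) {
    for (j in seq_along(p)) {
      pre <- p[seq_len(j - 1)]
      phi[p[j]] <- phi[p[j]] + v_memo(sort(c(pre, p[j]))) - v_memo(sort(pre))
    }
  }
  phi / length(perms)
}

# A small random two-layer ReLU head over M groups of `d` features,
# mirroring the classifier head's form but with free weights.
random_head <- function(M, d, hidden = 8, seed = 0) {
  withr::with_seed(seed, {
    W <- matrix(rnorm(M * d * hidden, sd = 0.5), M * d, hidden)
    b <- rnorm(hidden, sd = 0.1)
    w2 <- rnorm(hidden, sd = 0.5)
  })
  function(Z) {
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
    H <- pmax(sweep(Z %*% W, 2, b, "+"), 0)
    as.vector(1 / (1 + exp(-(H %*% w2))))
  }
}
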