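# Internal helpers shared across modules.

# 32-bit FNV-1a hash of a string, folded into [0, 2^31 - 1].
# Used to derive stable per-entity RNG substreams from a single master seed,
# so that e.g. plant "p007" always receives the same rendering stream
# regardless of how many plants are simulated.
stable_hash <- function(x) {
  stopifnot(length(x) == 1L)
  bytes <- utf8ToInt(as.character(x))
  h <- 2166136261
  for (b in bytes) {
    # XOR with the low byte (b < 256), in double arithmetic
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so every intermediate stays exactly representable
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Combine a master seed with a character tag into a derived seed < 2^31.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + stable_hash(tag)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data frame as CSV with stable formatting (no row names, no quoting
# surprises) so that re-runs are byte-identical.
write_csv_stable <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
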