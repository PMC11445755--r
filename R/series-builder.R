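# Harvest-day-anchored time-series construction.
#
# A plant that becomes Ready at harvest day k yields k series: one anchored
# at each earlier harvest day (labelled Not-ready) and one at its readiness
# day (labelled Ready). Each series consists of the basic image at the
# anchoring acquisition day plus the T-1 chronologically preceding images,
# i.e. a trailing window over the acquisition grid ending at the anchor.

#' Read an observation manifest
#'
#' @param path Path to a CSV with columns `plant_id, dap, image_path,
#'   ready_hd`. Image paths are interpreted relative to the manifest's
#'   directory.
#' @return A tibble with an attribute `root` (the manifest directory).
#' @export
read_manifest <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_manifest(df)
  attr(df, "root") <- dirname(path)
  df
}

validate_manifest <- function(manifest) {
  need <- c("plant_id", "dap", "image_path", "ready_hd")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    abort(paste0("Manifest is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest[c("plant_id", "dap")])) {
    abort("Manifest has duplicate (plant_id, dap) records.")
  }
  per_plant <- tapply(manifest$ready_hd, manifest$plant_id, function(x) length(unique(x)))
  if (any(per_plant != 1L)) {
    abort("Each plant must have a single ready_hd across its records.")
  }
  invisible(manifest)
}

#' Build labelled, harvest-day-anchored image time series
#'
#' For every plant with readiness day `k`, emits exactly `k` series anchored
#' at harvest days 1..k. A series anchored at harvest day `j` uses the basic
#' image at that day's anchoring acquisition day plus the `T - 1`
#' chronologically preceding acquisition days, and is labelled `Ready` iff
#' `j == k`. The four anchoring acquisition days are the last four days of
#' the manifest's acquisition grid.
#'
#' @param manifest Observation manifest (see [read_manifest()]).
#' @param T Series length; must not exceed the available history of any
#'   emitted anchor (8 on the default 11-day grid, which is constrained by
#'   the first harvest day's anchor).
#' @return A list of `series_sample` objects with attributes `grid` (the
#'   acquisition grid) and `anchor_daps`.
#' @export
build_series <- function(manifest, T) {
  validate_manifest(manifest)
  grid <- sort(unique(manifest$dap))
  anchor_daps <- tail(grid, 4L)
  T <- as.integer(T)
  if (T < 1L) abort("`T` must be at least 1.")
  plants <- manifest[!duplicated(manifest$plant_id), c("plant_id", "ready_hd")]
  path_of <- setNames(manifest$image_path, paste(manifest$plant_id, manifest$dap))
  samples <- list()
  idx <- 1L
  for (i in seq_len(nrow(plants))) {
    pid <- plants$plant_id[i]
    k <- plants$ready_hd[i]
    if (!(k %in% 1:4)) abort(sprintf("Plant %s has invalid ready_hd %s.", pid, k))
    for (j in seq_len(k)) {
      anchor <- anchor_daps[j]
      avail <- grid[grid <= anchor]
      if (T > length(avail)) {
        abort(sprintf(
          "T = %d exceeds the %d acquisition days available before the HD_%d anchor (DAP %d).",
          T, length(avail), j, anchor
        ))
      }
      window <- tail(avail, T)
      keys <- paste(pid, window)
      if (any(!keys %in% names(path_of))) {
        abort(sprintf("Missing image record for plant %s at DAP %s.",
                      pid, paste(window[!keys %in% names(path_of)], collapse = ", ")))
      }
      samples[[idx]] <- new_series_sample(
        plant_id = pid, anchor_hd = j, daps = window,
        image_paths = unname(path_of[keys]),
        label = if (j == k) "Ready" else "Not-ready"
      )
      idx <- idx + 1L
    }
  }
  attr(samples, "grid") <- grid
  attr(samples, "anchor_daps") <- anchor_daps
  samples
}

new_series_sample <- function(plant_id, anchor_hd, daps, image_paths, label,
                              ops = character(0)) {
  stopifnot(length(daps) == length(image_paths), all(diff(daps) > 0))
  structure(
    list(plant_id = plant_id, anchor_hd = as.integer(anchor_hd),
         daps = as.integer(daps), image_paths = image_paths,
         label = label, T = length(daps), ops = ops),
    class = "series_sample"
  )
}

#' @export
print.series_sample <- function(x, ...) {
  cat(sprintf("<series_sample> plant %s, anchor HD_%d, T = %d, label %s\n",
              x$plant_id, x$anchor_hd, x$T, x$label))
  cat("  DAPs:", paste(x$daps, collapse = ", "), "\n")
  if (length(x$ops)) cat("  ops: ", paste(x$ops, collapse = " -> "), "\n")
  invisible(x)
}

series_ops <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")

#' Apply a geometric transform to an image array
#'
#' Rotations are clockwise. Operates on 2-d matrices or h x w x c arrays.
#'
#' @param img Image matrix or array.
#' @param ops Character vector of operations, applied in order; any of
#'   `identity`, `hflip`, `vflip`, `rot90`, `rot180`, `rot270`.
#' @return Transformed image of the same type.
#' @export
apply_image_ops <- function(img, ops) {
  bad <- setdiff(ops, series_ops)
  if (length(bad)) abort(paste0("Unknown augmentation op(s): ", paste(bad, collapse = ", ")))
  rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  one <- function(m, op) {
    switch(op,
      identity = m,
      hflip = m[, ncol(m):1, drop = FALSE],
      vflip = m[nrow(m):1, , drop = FALSE],
      rot90 = rot_cw(m),
      rot180 = rot_cw(rot_cw(m)),
      rot270 = rot_cw(rot_cw(rot_cw(m)))
    )
  }
  apply_mat <- function(m) Reduce(one, ops, accumulate = FALSE, init = m)
  if (length(dim(img)) == 3L) {
    first <- apply_mat(img[, , 1])
    out <- array(0, c(dim(first), dim(img)[3]))
    out[, , 1] <- first
    for (c in seq_len(dim(img)[3])[-1]) out[, , c] <- apply_mat(img[, , c])
    out
  } else {
    apply_mat(img)
  }
}

#' Augment an entire series with one shared geometric transform
#'
#' Every image in the series receives the identical transform, preserving
#' temporal consistency; labels and acquisition days are unchanged. The
#' transform is recorded on the sample and applied lazily when images are
#' loaded.
#'
#' @param sample A `series_sample`.
#' @param ops Character vector of geometric operations (see
#'   [apply_image_ops()]). Without `seed` they are appended in order; with a
#'   `seed`, a single operation is drawn uniformly from `ops`.
#' @param seed Optional seed for random selection from `ops`.
#' @return The augmented `series_sample`.
#' @export
apply_series_augmentation <- function(sample, ops, seed = NULL) {
  stopifnot(inherits(sample, "series_sample"))
  bad <- setdiff(ops, series_ops)
  if (length(bad)) abort(paste0("Unknown augmentation op(s): ", paste(bad, collapse = ", ")))
  if (!is.null(seed)) {
    ops <- with_seed(seed, sample(ops, 1L))
  }
  sample$ops <- c(sample$ops, ops)
  sample
}

#' Restrict a series to a subset of acquisition days
#'
#' Order is preserved and the anchoring (basic-image) day must be kept:
#' the last image of a series is the reference immediately before the
#' potential harvest, without which the label is undefined.
#'
#' @param sample A `series_sample`.
#' @param keep_daps Days to keep (subset of `sample$daps`).
#' @return A `series_sample` with `T = length(intersect(daps, keep_daps))`.
#' @export
subset_series <- function(sample, keep_daps) {
  stopifnot(inherits(sample, "series_sample"))
  keep_daps <- as.integer(keep_daps)
  if (!all(keep_daps %in% sample$daps)) {
    abort("`keep_daps` must be a subset of the sample's acquisition days.")
  }
  anchor <- sample$daps[sample$T]
  if (!(anchor %in% keep_daps)) {
    abort(sprintf("Cannot drop the anchoring basic-image DAP %d.", anchor))
  }
  keep <- sample$daps %in% keep_daps
  new_series_sample(sample$plant_id, sample$anchor_hd, sample$daps[keep],
                    sample$image_paths[keep], sample$label, sample$ops)
}

#' Split a manifest into disjoint plant-level subsets
#'
#' A plant contributes up to four series; splitting at plant level prevents
#' leakage of the same plant across training and validation.
#'
#' @param manifest Observation manifest.
#' @param val_frac,test_frac Fractions of plants assigned to validation and
#'   test.
#' @param seed Seed for the plant permutation.
#' @return A named list of manifests (`train`, `val`, and `test` if
#'   `test_frac > 0`).
#' @export
split_plants <- function(manifest, val_frac = 0.2, test_frac = 0, seed = 0L) {
  validate_manifest(manifest)
  if (val_frac < 0 || test_frac < 0 || val_frac + test_frac >= 1) {
    abort("Split fractions must be non-negative and sum to less than 1.")
  }
  plants <- sort(unique(manifest$plant_id))
  n <- length(plants)
  perm <- with_seed(derive_seed(seed, "plant_split"), sample(plants))
  n_val <- round(val_frac * n)
  n_test <- round(test_frac * n)
  val_ids <- perm[seq_len(n_val)]
  test_ids <- if (n_test > 0) perm[n_val + seq_len(n_test)] else character(0)
  train_ids <- setdiff(plants, c(val_ids, test_ids))
  if (!length(train_ids) || !length(val_ids)) abort("Split produced an empty subset.")
  keep_root <- function(ids) {
    out <- manifest[manifest$plant_id %in% ids, , drop = FALSE]
    attr(out, "root") <- attr(manifest, "root")
    out
  }
  out <- list(train = keep_root(train_ids), val = keep_root(val_ids))
  if (n_test > 0) out$test <- keep_root(test_ids)
  out
}

#' Write a series index as JSON lines
#'
#' One JSON object per line per series: plant id, anchoring harvest day,
#' acquisition days, image paths, label, length and recorded augmentations.
#'
#' @param samples List of `series_sample` objects.
#' @param path Output path.
#' @export
write_series_index <- function(samples, path) {
  lines <- vapply(samples, function(s) {
    jsonlite::toJSON(list(
      plant_id = jsonlite::unbox(s$plant_id),
      anchor_hd = jsonlite::unbox(s$anchor_hd),
      daps = s$daps, image_paths = s$image_paths,
      label = jsonlite::unbox(s$label), T = jsonlite::unbox(s$T),
      ops = s$ops
    ), digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a series index written by [write_series_index()]
#'
#' @param path Path to a JSON-lines series index.
#' @return A list of `series_sample` objects.
#' @export
read_series_index <- function(path) {
  lines <- readLines(path)
  samples <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    new_series_sample(x$plant_id, x$anchor_hd, x$daps, x$image_paths, x$label,
                      ops = as.character(x$ops))
  })
  grids <- sort(unique(unlist(lapply(samples, `[[`, "daps"))))
  attr(samples, "grid") <- grids
  samples
}
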