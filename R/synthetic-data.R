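# Synthetic field generator: plant growth truths, rendered images, manifests.
#
# The generator emulates the structure of a UAV cauliflower trial: a fixed
# grid of acquisition days (days after planting, DAP), four potential
# harvest days anchored at the last four acquisition days, one readiness
# transition per plant, growth-correlated image content, and per-day
# nuisance variation (weather/exposure).

#' Default acquisition-day grid
#'
#' Eleven acquisition days (days after planting) spanning leaf development
#' to harvest, with the four potential harvest days anchored at the last
#' four entries (DAP 69, 71, 76, 80).
#'
#' @return Integer vector of length 11.
#' @export
default_acquisition_daps <- function() {
  c(22L, 27L, 35L, 44L, 50L, 57L, 65L, 69L, 71L, 76L, 80L)
}

#' Growth and rendering parameters for a simulated field
#'
#' Bundles every knob of the synthetic-data generator. Head growth follows a
#' per-plant logistic curve `size(dap) = K / (1 + exp(-r (dap - t0)))` with
#' asymptotic head diameter `K` (cm), growth rate `r` (1/day) and maturity
#' midpoint `t0` (DAP). A plant is Ready at the first harvest day whose
#' anchoring acquisition day shows a head of at least `ready_threshold_cm`;
#' plants never reaching the threshold are harvested (and labelled Ready)
#' on the final day. The default midpoint spread is chosen so that roughly
#' half of the still-standing plants mature by each harvest day, keeping the
#' two readiness classes near balance at every decision point.
#'
#' @param n_plants Number of plants (positive integer).
#' @param acquisition_daps Strictly increasing integer vector of acquisition
#'   days after planting.
#' @param harvest_days Integer vector of 4 indices into `acquisition_daps`
#'   giving the basic-image (anchor) day of each harvest day; must be the
#'   last four grid positions.
#' @param image_size Image side length in pixels.
#' @param informative_daps Subset of `acquisition_daps` whose images carry
#'   label signal (a rendered head whose radius and brightness track the
#'   plant's own latent head size). At every other day, head sizes are
#'   permuted across plants before rendering, destroying the association
#'   with the plant's own trajectory while preserving per-day image
#'   statistics.
#' @param noise_level Standard deviation of additive pixel noise.
#' @param ready_threshold_cm Head diameter (cm) at the anchoring day at
#'   which a plant counts as Ready.
#' @param growth_rate_mean,growth_rate_sd Per-plant logistic growth rate
#'   distribution (1/day).
#' @param readiness_hazard Probability that a plant still standing at a
#'   harvest day matures by it. The maturity midpoint `t0` is drawn so that
#'   this hazard holds at every harvest day despite the uneven harvest
#'   spacing, keeping the two classes near balance at each decision point;
#'   the within-field developmental spread follows from the hazard and the
#'   spread windows below.
#' @param early_spread_days Width (days) of the maturity window of plants
#'   already ready before the first harvest day.
#' @param late_spread_days Width (days) of the maturity window of plants
#'   not ready by the last harvest day (cleared and labelled Ready there).
#' @param head_cap_mean,head_cap_sd Per-plant asymptotic head diameter
#'   distribution (cm).
#' @param signal_free Set `TRUE` to explicitly request a dataset without any
#'   informative acquisition day (negative control); otherwise an empty
#'   `informative_daps` is an error.
#' @param seed Master seed; all randomness (growth draws, permutations,
#'   nuisance factors, pixel noise) flows from it through named substreams.
#'
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(n_plants,
                          acquisition_daps = default_acquisition_daps(),
                          harvest_days = NULL,
                          image_size = 64L,
                          informative_daps = acquisition_daps,
                          noise_level = 0.05,
                          ready_threshold_cm = 10,
                          growth_rate_mean = 0.18,
                          growth_rate_sd = 0.01,
                          readiness_hazard = 0.5,
                          early_spread_days = 8,
                          late_spread_days = 5,
                          head_cap_mean = 13,
                          head_cap_sd = 0.5,
                          signal_free = FALSE,
                          seed = 0L) {
  if (length(n_plants) != 1L || !is.finite(n_plants) || n_plants < 1) {
    abort("`n_plants` must be a positive integer.")
  }
  acquisition_daps <- as.integer(acquisition_daps)
  if (any(diff(acquisition_daps) <= 0)) {
    abort("`acquisition_daps` must be strictly increasing.")
  }
  n_days <- length(acquisition_daps)
  if (n_days < 5L) abort("Need at least 5 acquisition days (4 anchors + history).")
  if (is.null(harvest_days)) harvest_days <- (n_days - 3L):n_days
  harvest_days <- as.integer(harvest_days)
  if (length(harvest_days) != 4L || !identical(harvest_days, (n_days - 3L):n_days)) {
    abort("`harvest_days` must index the last four acquisition days.")
  }
  if (signal_free) {
    informative_daps <- integer(0)
  }
  informative_daps <- as.integer(informative_daps)
  if (!signal_free && length(informative_daps) == 0L) {
    abort(paste0(
      "`informative_daps` is empty; a signal-free dataset must be requested ",
      "explicitly via `signal_free = TRUE`."
    ))
  }
  if (!all(informative_daps %in% acquisition_daps)) {
    abort("`informative_daps` must be a subset of `acquisition_daps`.")
  }
  if (noise_level < 0) abort("`noise_level` must be non-negative.")
  structure(
    list(
      n_plants = as.integer(n_plants),
      acquisition_daps = acquisition_daps,
      harvest_days = harvest_days,
      anchor_daps = acquisition_daps[harvest_days],
      image_size = as.integer(image_size),
      informative_daps = informative_daps,
      noise_level = noise_level,
      ready_threshold_cm = ready_threshold_cm,
      growth_rate_mean = growth_rate_mean,
      growth_rate_sd = growth_rate_sd,
      readiness_hazard = readiness_hazard,
      early_spread_days = early_spread_days,
      late_spread_days = late_spread_days,
      head_cap_mean = head_cap_mean,
      head_cap_sd = head_cap_sd,
      signal_free = signal_free,
      seed = as.integer(seed)
    ),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat("  plants:           ", x$n_plants, "\n")
  cat("  acquisition DAPs: ", paste(x$acquisition_daps, collapse = ", "), "\n")
  cat("  anchor DAPs:      ", paste(x$anchor_daps, collapse = ", "), "\n")
  cat("  informative DAPs: ",
      if (length(x$informative_daps)) paste(x$informative_daps, collapse = ", ")
      else "(none - signal free)", "\n")
  cat("  image size:       ", x$image_size, "px\n")
  cat("  seed:             ", x$seed, "\n")
  invisible(x)
}

# Latent per-plant growth truths. One RNG substream per plant, derived by
# stable hashing of the plant id, so truths are independent of n_plants
# ordering and fully reproducible.
#
# The maturity midpoint t0 is drawn by inverse CDF from a piecewise-uniform
# distribution whose breakpoints are the harvest anchors shifted back by the
# mean days between the maturity midpoint and threshold crossing
# (logit(threshold / head_cap) / growth_rate). Segment masses follow a
# constant per-harvest-day hazard, so each harvest day matures the same
# fraction of the still-standing field regardless of the uneven harvest
# spacing.
plant_truths <- function(params) {
  h <- params$readiness_hazard
  seg_w <- c(h, h * (1 - h), h * (1 - h)^2, h * (1 - h)^3, (1 - h)^4)
  seg_cum <- cumsum(seg_w)
  ids <- sprintf("p%04d", seq_len(params$n_plants))
  rows <- lapply(ids, function(id) {
    with_seed(derive_seed(params$seed, paste0("plant_", id)), {
      r <- max(0.05, rnorm(1, params$growth_rate_mean, params$growth_rate_sd))
      k <- max(params$ready_threshold_cm + 1, rnorm(1, params$head_cap_mean, params$head_cap_sd))
      # this plant's own midpoint-to-threshold offset and readiness breakpoints
      thr_frac <- params$ready_threshold_cm / k
      delta <- log(thr_frac / (1 - thr_frac)) / r
      breaks <- params$anchor_daps - delta
      seg_lo <- c(breaks[1] - params$early_spread_days, breaks)
      seg_hi <- c(breaks, breaks[4] + params$late_spread_days)
      u <- runif(1)
      seg <- findInterval(u, seg_cum) + 1L
      frac <- (u - c(0, seg_cum)[seg]) / seg_w[seg]
      t0 <- seg_lo[seg] + frac * (seg_hi[seg] - seg_lo[seg])
      list(plant_id = id, growth_rate = r, midpoint = t0, head_cap = k)
    })
  })
  truth <- dplyr::bind_rows(lapply(rows, as_tibble))
  sizes <- vapply(seq_len(nrow(truth)), function(i) {
    head_size_at(truth$head_cap[i], truth$growth_rate[i], truth$midpoint[i],
                 params$acquisition_daps)
  }, numeric(length(params$acquisition_daps)))
  sizes <- t(sizes) # plants x daps
  colnames(sizes) <- paste0("size_d", params$acquisition_daps)
  anchor_sizes <- sizes[, paste0("size_d", params$anchor_daps), drop = FALSE]
  ready_hd <- apply(anchor_sizes >= params$ready_threshold_cm, 1L, function(z) {
    j <- which(z)
    if (length(j)) j[1L] else 4L # never-ready plants are cleared on the last day
  })
  truth$ready_hd <- as.integer(ready_hd)
  truth$head_size_by_dap <- lapply(seq_len(nrow(sizes)), function(i) {
    setNames(sizes[i, ], as.character(params$acquisition_daps))
  })
  truth
}

head_size_at <- function(k, r, t0, dap) {
  k / (1 + exp(-r * (dap - t0)))
}

#' Simulate a field of plants with rendered images and a manifest
#'
#' Draws per-plant growth truths, assigns each plant its readiness harvest
#' day by thresholding the latent head-size trajectory at the anchoring
#' acquisition days, renders one RGB PNG per plant per acquisition day, and
#' writes a `manifest.csv` (columns `plant_id, dap, image_path, ready_hd`;
#' image paths relative to `out_dir`). Only `informative_daps` are rendered
#' from the plant's own head size; at all other days the sizes are permuted
#' across plants, so those images carry no information about the plant's own
#' readiness. Per-day brightness/soil nuisance is shared across plants,
#' mimicking changing weather between flights. Byte-identical output for
#' identical parameters and seed.
#'
#' @param params A [growth_params()] object.
#' @param out_dir Output directory (created if missing); images go to
#'   `out_dir/images/`.
#' @return Invisibly, a list with elements `manifest` (tibble), `truth`
#'   (tibble with per-plant latents, readiness day and head-size
#'   trajectory), `params`, and `dir`.
#' @export
simulate_field <- function(params, out_dir) {
  stopifnot(inherits(params, "growth_params"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  truth <- plant_truths(params)
  n <- params$n_plants
  daps <- params$acquisition_daps
  dap_min <- min(daps)
  dap_range <- max(daps) - dap_min

  size_mat <- do.call(rbind, truth$head_size_by_dap) # plants x daps (true sizes)
  rendered <- size_mat
  for (j in seq_along(daps)) {
    if (!(daps[j] %in% params$informative_daps)) {
      perm <- with_seed(derive_seed(params$seed, paste0("shuffle_", daps[j])),
                        sample.int(n))
      rendered[, j] <- size_mat[perm, j]
    }
  }

  nuisance <- lapply(daps, function(d) {
    with_seed(derive_seed(params$seed, paste0("nuisance_", d)), {
      list(brightness = runif(1, 0.85, 1.15), tone = runif(1, -0.06, 0.06))
    })
  })

  rows <- vector("list", n * length(daps))
  k <- 1L
  for (i in seq_len(n)) {
    id <- truth$plant_id[i]
    for (j in seq_along(daps)) {
      d <- daps[j]
      rel <- file.path("images", sprintf("%s_d%03d.png", id, d))
      img <- render_plant_image(
        size_cm = rendered[i, j],
        age_frac = (d - dap_min) / max(1, dap_range),
        image_size = params$image_size,
        brightness = nuisance[[j]]$brightness,
        tone = nuisance[[j]]$tone,
        noise_level = params$noise_level,
        seed = derive_seed(params$seed, paste0("img_", id, "_", d))
      )
      png::writePNG(img, file.path(out_dir, rel))
      rows[[k]] <- list(plant_id = id, dap = d, image_path = rel,
                        ready_hd = truth$ready_hd[i])
      k <- k + 1L
    }
  }
  manifest <- dplyr::bind_rows(lapply(rows, as_tibble))
  write_csv_stable(manifest, file.path(out_dir, "manifest.csv"))

  truth_flat <- truth
  truth_flat$head_size_by_dap <- NULL
  truth_flat <- dplyr::bind_cols(
    truth_flat,
    as_tibble(do.call(rbind, truth$head_size_by_dap), .name_repair = function(x) paste0("size_d", x))
  )
  write_csv_stable(truth_flat, file.path(out_dir, "truth.csv"))

  invisible(list(manifest = manifest, truth = truth, params = params, dir = out_dir))
}

# Parametric plant renderer: soil background with per-day nuisance, a green
# leaf rosette whose extent tracks plant age, and a central pale disc whose
# radius and brightness track head size. Values in [0, 1], 8-bit RGB on disk.
render_plant_image <- function(size_cm, age_frac, image_size, brightness,
                               tone, noise_level, seed) {
  s <- image_size
  ax <- seq(-1, 1, length.out = s)
  xx <- matrix(ax, s, s)
  yy <- t(xx)
  rr <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx)
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    petals <- sample(7:9, 1)
    jitter <- runif(1, 0.95, 1.05)
    noise <- matrix(rnorm(s * s, 0, noise_level), s, s)

    # soil
    tex <- 0.03 * sin(6 * pi * xx + phase) * cos(5 * pi * yy - phase)
    r_ch <- (0.36 + tone) * brightness + tex + noise
    g_ch <- (0.27 + 0.5 * tone) * brightness + tex + noise
    b_ch <- 0.18 * brightness + tex + noise

    # leaf rosette, radius grows with age
    r_leaf <- jitter * (0.30 + 0.55 * age_frac)
    leaf <- rr < r_leaf * (0.78 + 0.22 * cos(petals * th + phase))
    r_ch[leaf] <- (0.14 + 0.3 * tone) * brightness + noise[leaf]
    g_ch[leaf] <- (0.45 + 0.1 * age_frac) * brightness + noise[leaf]
    b_ch[leaf] <- 0.16 * brightness + noise[leaf]

    # head disc: radius and brightness track head size (cm)
    r_head <- 0.05 + 0.022 * size_cm
    edge <- pmin(1, pmax(0, (r_head - rr) / 0.04))
    lum <- (0.55 + 0.025 * size_cm) * brightness
    r_ch <- r_ch * (1 - edge) + edge * (lum + noise)
    g_ch <- g_ch * (1 - edge) + edge * (lum + noise)
    b_ch <- b_ch * (1 - edge) + edge * (0.92 * lum + noise)
  })
  img <- array(0, dim = c(s, s, 3))
  img[, , 1] <- r_ch
  img[, , 2] <- g_ch
  img[, , 3] <- b_ch
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# -- Developmental-stage lookup -----------------------------------------------

# Mean head size (cm) per harvest day per acquisition day, as observed in the
# reference field trial; NA marks plants already harvested at that day.
head_size_reference <- function() {
  tibble(
    dap = c(44L, 50L, 57L, 65L, 69L, 71L, 76L, 80L),
    hd1 = c(0.9, 0.9, 2.1, 7.7, 10.9, NA, NA, NA),
    hd2 = c(0.7, 0.8, 1.9, 6.1, 8.8, 12.0, NA, NA),
    hd3 = c(0.4, 0.5, 1.6, 4.6, 6.7, 9.4, 13.5, NA),
    hd4 = c(0.1, 0.2, 1.2, 3.3, 5.6, 7.3, 10.0, 12.2)
  )
}

#' Developmental-stage (BBCH) code implied by mean head size
#'
#' Maps an (acquisition day, harvest day) cell of the reference mean
#' head-size table to a BBCH code: heads of 1 cm or less are still in main
#' shoot development (`"3x"`); above that the micro stage within macro
#' stage 4 follows the fraction of the expected final head diameter reached
#' (>1 cm: 41, >=30%: 43, >=50%: 45, >=70%: 47, >=80%: 48, >=95%: 49).
#' The expected diameter of a harvest day is its final observed mean head
#' size. Used for reporting only.
#'
#' @param dap Acquisition day (must have a reference row).
#' @param hd Harvest day in 1..4.
#' @return A BBCH code string such as `"3x"` or `"45"`.
#' @export
stage_lookup <- function(dap, hd) {
  stopifnot(length(dap) == 1L, length(hd) == 1L)
  if (!(hd %in% 1:4)) abort("`hd` must be in 1..4.")
  ref <- head_size_reference()
  col <- paste0("hd", hd)
  row <- which(ref$dap == dap)
  if (length(row) == 0L) {
    abort(sprintf("No head-size reference for DAP %s.", dap))
  }
  size <- ref[[col]][row]
  if (is.na(size)) {
    abort(sprintf("Head-size cell absent for DAP %s, HD %s (plants already harvested).",
                  dap, hd))
  }
  expected <- max(ref[[col]], na.rm = TRUE)
  if (size <= 1) return("3x")
  frac <- size / expected
  if (frac >= 0.95) "49"
  else if (frac >= 0.8) "48"
  else if (frac >= 0.7) "47"
  else if (frac >= 0.5) "45"
  else if (frac >= 0.3) "43"
  else "41"
}
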