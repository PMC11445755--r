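test_that("overall accuracy matches hand arithmetic", {
  expect_equal(overall_accuracy(confusion_counts(50, 50, 0, 0)), 1.0)
  expect_equal(overall_accuracy(confusion_counts(0, 0, 50, 50)), 0.0)
  expect_equal(overall_accuracy(confusion_counts(30, 20, 20, 10)), 0.625)
  expect_error(overall_accuracy(confusion_counts(0, 0, 0, 0)), "empty")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("balanced accuracy is the macro-average of recalls", {
  expect_equal(balanced_accuracy(confusion_counts(25, 25, 0, 0)), 1.0)
  # degenerate all-Ready predictor on 75/25 data: recalls 1 and 0
  expect_equal(balanced_accuracy(confusion_counts(75, 0, 25, 0)), 0.5)
  expect_equal(balanced_accuracy(confusion_counts(30, 20, 20, 10)), 0.625)
  expect_error(balanced_accuracy(confusion_counts(0, 10, 5, 0)), "Ready")
  expect_error(balanced_accuracy(confusion_counts(10, 0, 0, 5)), "Not-ready")
})

test_that("on balanced data overall and balanced accuracy coincide", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      n <- 40
      truth <- rep(c(TRUE, FALSE), each = n / 2)
      pred <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(runif(1), 1))
      cc <- confusion_from_predictions(truth, pred)
      expect_equal(overall_accuracy(cc), balanced_accuracy(cc), tolerance = 1e-12)
    }
  })
})

test_that("balanced accuracy is invariant to duplicating every series", {
  withr::with_seed(5, {
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.7, 0.3))
    pred <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  })
  truth[1] <- TRUE; truth[2] <- FALSE # both classes present
  cc1 <- confusion_from_predictions(truth, pred)
  cc3 <- confusion_from_predictions(rep(truth, 3), rep(pred, 3))
  expect_equal(balanced_accuracy(cc1), balanced_accuracy(cc3))
})

test_that("label vectors are validated", {
  expect_error(confusion_from_predictions(c("Ready", "Weird"), c("Ready", "Ready")),
               "Unknown class")
  expect_error(confusion_from_predictions(c(TRUE, FALSE), TRUE), "equal length")
  cc <- confusion_from_predictions(c("Ready", "Not-ready"), c("Ready", "Ready"))
  expect_equal(cc$tp, 1)
  expect_equal(cc$fp, 1)
})

test_that("report writes a complete, idempotent bundle", {
  mk <- function(phi, daps, hd, pid) {
    harvshap:::new_group_shap_result(0.1, phi, 0.1 + sum(phi), "exact",
                                     daps = daps, anchor_hd = hd, plant_id = pid)
  }
  res <- structure(list(
    mk(c(0.2, -0.1, 0.3), c(44, 50, 69), 1L, "p1"),
    mk(c(0.1, 0.2, -0.4), c(44, 50, 71), 2L, "p2"),
    mk(c(0, 0.25, 0.15), c(44, 50, 71), 2L, "p3")
  ), class = "group_shap_results")
  summ <- summarize_contributions(res)
  curve <- tibble::tibble(family = c("baseline", "iTS"), T = c(1, 2),
                          oaacc = c(0.7, 0.8), bcacc = c(0.69, 0.81))
  trace <- tibble::tibble(step = 1:2, excluded_dap = c(50L, 44L),
                          mean_abs_phi = c(0.01, 0.02), T = c(7L, 6L),
                          oaacc = c(0.8, 0.82), bcacc = c(0.79, 0.8),
                          remaining_daps = c("a", "b"), bbch_stages = c("x", "y"))
  out1 <- file.path(tempdir(), "report1")
  out2 <- file.path(tempdir(), "report2")
  report(list(shap = summ, curve = curve, trace = trace), out1)
  report(list(shap = summ, curve = curve, trace = trace), out2)
  for (f in c("shap_summary.csv", "shap_by_dap.csv", "accuracy_curve.csv",
              "exclusion_order.csv", "report.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
  # exclusion table has one row per excluded day
  tab <- read.csv(file.path(out1, "exclusion_order.csv"))
  expect_equal(nrow(tab), 2)

  # empty attribution refuses to render
  empty <- list(shap = list(per_hd = summ$per_hd[0, ], by_dap = summ$by_dap[0, ]))
  expect_error(report(empty, file.path(tempdir(), "report3")), "No attribution")
  expect_error(report(list(), file.path(tempdir(), "report4")), "No artifacts")
})

test_that("reported quantiles agree with an independent percentile routine", {
  mk <- function(phi, daps, hd, pid) {
    harvshap:::new_group_shap_result(0, phi, sum(phi), "exact",
                                     daps = daps, anchor_hd = hd, plant_id = pid)
  }
  withr::with_seed(6, {
    res <- structure(lapply(1:40, function(i) {
      mk(rnorm(3), c(44, 50, 69), 1L, paste0("p", i))
    }), class = "group_shap_results")
  })
  summ <- summarize_contributions(res)
  phis_44 <- vapply(res, function(r) r$phi[[1]], numeric(1))
  # independent percentile: linear interpolation of the sorted sample
  indep_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  row <- summ$per_hd[summ$per_hd$hd == "1" & summ$per_hd$dap == 44, ]
  for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    col <- paste0("q", sprintf("%02d", p * 100))
    expect_equal(row[[col]], indep_q(phis_44, p), tolerance = 1e-9)
  }
})
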