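# Accuracy metrics and report rendering. Positive class is Ready throughout.

#' Confusion-matrix counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts; the positive class is
#'   Ready.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,predicted Logical vectors (`TRUE` = Ready) or character /
#'   factor vectors with levels `"Ready"` / `"Not-ready"`.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  as_ready <- function(x) {
    if (is.logical(x)) return(x)
    x <- as.character(x)
    bad <- setdiff(unique(x), c("Ready", "Not-ready"))
    if (length(bad)) abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", ")))
    x == "Ready"
  }
  t <- as_ready(truth)
  p <- as_ready(predicted)
  if (length(t) != length(p)) abort("`truth` and `predicted` must have equal length.")
  confusion_counts(tp = sum(t & p), tn = sum(!t & !p),
                   fp = sum(!t & p), fn = sum(t & !p))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  TN %d  FP %d  FN %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Overall accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion_counts()] object.
#' @return Accuracy in \[0, 1\].
#' @export
overall_accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) abort("Cannot compute accuracy from empty counts.")
  (c$tp + c$tn) / total
}

#' Balanced class accuracy (macro-average of recalls)
#'
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`. If either class is absent its recall is
#' undefined and the function errors rather than silently returning 0.
#'
#' @param c A [confusion_counts()] object.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0) abort("No Ready series: recall of the positive class is undefined.")
  if (c$tn + c$fp == 0) abort("No Not-ready series: recall of the negative class is undefined.")
  (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp)) / 2
}

#' Render a machine-readable report bundle for a pipeline run
#'
#' Writes, into `out_dir`: the accuracy-versus-length table
#' (`accuracy_curve.csv`), per-day per-harvest-day Shapley quantile
#' summaries (`shap_summary.csv`, the numbers behind violin-style plots),
#' and the exclusion-order table annotated with developmental stages
#' (`exclusion_order.csv`), plus a `report.json` collecting headline
#' numbers. Re-running on the same artifacts is byte-identical.
#'
#' @param artifacts A list with any of: `curve` (tibble from
#'   [accuracy_curve()]), `shap` (result of [summarize_contributions()]),
#'   `trace` (a [run_selection()] trace).
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
report <- function(artifacts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  headline <- list()
  if (!is.null(artifacts$shap)) {
    if (!nrow(artifacts$shap$per_hd)) {
      abort("No attribution available: Shapley summary is empty.")
    }
    p <- file.path(out_dir, "shap_summary.csv")
    write_csv_stable(artifacts$shap$per_hd, p)
    written <- c(written, p)
    p <- file.path(out_dir, "shap_by_dap.csv")
    write_csv_stable(artifacts$shap$by_dap, p)
    written <- c(written, p)
    headline$lowest_contribution_dap <- artifacts$shap$argmin_dap
  }
  if (!is.null(artifacts$curve)) {
    p <- file.path(out_dir, "accuracy_curve.csv")
    write_csv_stable(artifacts$curve, p)
    written <- c(written, p)
    best <- artifacts$curve[which.max(artifacts$curve$oaacc), ]
    headline$best_family <- best$family
    headline$best_T <- best$T
    headline$best_oaacc <- best$oaacc
  }
  if (!is.null(artifacts$trace)) {
    tr <- as_tibble(artifacts$trace)
    p <- file.path(out_dir, "exclusion_order.csv")
    write_csv_stable(tr, p)
    written <- c(written, p)
    headline$n_excluded <- nrow(tr)
    headline$exclusion_order <- tr$excluded_dap
  }
  if (!length(written)) abort("No artifacts supplied to report.")
  p <- file.path(out_dir, "report.json")
  write_json_stable(headline, p)
  written <- c(written, p)
  invisible(written)
}
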