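#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(v)), names = names(v),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (recall, true-positive rate) `Tp/(Tp+Fn)`, specificity
#' `Tn/(Tn+Fp)`, precision `Tp/(Tp+Fp)`, f1-score (harmonic mean of precision
#' and sensitivity) and accuracy defined as the *balanced* accuracy
#' `(recall + specificity)/2`. All values are proportions in `[0, 1]`;
#' report-time percentage rounding is a separate step ([metrics_percent()]).
#' A zero denominator yields `NA` (an undefined-metric sentinel), never a
#' silent 0.
#'
#' @param counts a [confusion_counts()].
#' @return Object of class `classification_metrics`: named list with
#'   `sensitivity`, `specificity`, `precision`, `f1`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  stv <- rat(counts$tp, counts$tp + counts$fn)
  spc <- rat(counts$tn, counts$tn + counts$fp)
  prc <- rat(counts$tp, counts$tp + counts$fp)
  f1 <- if (!is.na(prc) && !is.na(stv) && (prc + stv) > 0) {
    2 * prc * stv / (prc + stv)
  } else NA_real_
  acc <- if (!is.na(stv) && !is.na(spc)) (stv + spc) / 2 else NA_real_
  structure(list(sensitivity = stv, specificity = spc, precision = prc,
                 f1 = f1, accuracy = acc),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  pc <- metrics_percent(x)
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%  precision %.1f%%  f1 %.1f%%  accuracy %.1f%%\n",
    pc["sensitivity"], pc["specificity"], pc["precision"], pc["f1"],
    pc["accuracy"]))
  invisible(x)
}

#' Metrics as percentages at report precision
#'
#' @param metrics a `classification_metrics` object (or named list of
#'   proportions).
#' @param digits decimal digits to round percentages to (default 1).
#' @return Named numeric vector of percentages.
#' @export
metrics_percent <- function(metrics, digits = 1) {
  round(100 * unlist(metrics, use.names = TRUE), digits)
}
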