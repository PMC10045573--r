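#' Confusion counts between two binary masks or label vectors
#'
#' @param y_true,y_pred Binary masks, arrays or vectors of 0/1 values with
#'   identical shape.
#' @return List of class `confusion_counts` with integers `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  a <- as.numeric(if (inherits(y_true, "binary_mask")) mask_values(y_true)
                  else y_true)
  b <- as.numeric(if (inherits(y_pred, "binary_mask")) mask_values(y_pred)
                  else y_pred)
  if (length(a) != length(b)) {
    stop("compared masks/vectors differ in size", call. = FALSE)
  }
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    stop("confusion counts require 0/1 values", call. = FALSE)
  }
  structure(list(tp = sum(a == 1 & b == 1),
                 fp = sum(a == 0 & b == 1),
                 fn = sum(a == 1 & b == 0),
                 tn = sum(a == 0 & b == 0)),
            class = "confusion_counts")
}

div_or <- function(num, den, fallback) {
  if (den == 0) fallback else num / den
}

#' Full evaluation-metric panel from confusion counts
#'
#' Dice (DSC), Jaccard (JSC), symmetric volume difference (`SVD = 1 - DSC`),
#' accuracy, sensitivity, specificity, precision, FPR, FNR, NPV, FDR, F1
#' and Matthews correlation.  Zero-denominator cases are assigned the value
#' the ideal classifier would attain there (1 for agreement-type metrics,
#' 0 for error rates, 0 for MCC when a margin vanishes) and flagged.
#'
#' @param counts A `confusion_counts` (or a list with `tp`, `fp`, `fn`,
#'   `tn`); alternatively pass `y_true` and `y_pred` to
#'   [confusion_counts()] first.
#' @return One-row tibble of metrics; the `"flags"` attribute names the
#'   metrics whose denominator was degenerate.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  flags <- character(0)
  flag <- function(name) flags <<- c(flags, name)

  dsc <- if (2 * tp + fp + fn == 0) { flag("dsc"); 1 } else
    2 * tp / (2 * tp + fp + fn)
  jsc <- if (tp + fp + fn == 0) { flag("jsc"); 1 } else
    tp / (tp + fp + fn)
  svd <- 1 - dsc
  accuracy <- (tp + tn) / total
  sensitivity <- if (tp + fn == 0) { flag("sensitivity"); 1 } else
    tp / (tp + fn)
  specificity <- if (tn + fp == 0) { flag("specificity"); 1 } else
    tn / (tn + fp)
  precision <- if (tp + fp == 0) { flag("precision"); 1 } else
    tp / (tp + fp)
  fpr <- if (fp + tn == 0) { flag("fpr"); 0 } else fp / (fp + tn)
  fnr <- if (fn + tp == 0) { flag("fnr"); 0 } else fn / (fn + tp)
  npv <- if (tn + fn == 0) { flag("npv"); 1 } else tn / (tn + fn)
  fdr <- if (fp + tp == 0) { flag("fdr"); 0 } else fp / (fp + tp)
  f1 <- if (precision + sensitivity == 0) { flag("f1"); 0 } else
    2 * precision * sensitivity / (precision + sensitivity)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) { flag("mcc"); 0 } else
    (tp * tn - fp * fn) / sqrt(mcc_den)

  out <- tibble::tibble(
    dsc = dsc, jsc = jsc, svd = svd, accuracy = accuracy,
    sensitivity = sensitivity, specificity = specificity,
    precision = precision, fpr = fpr, fnr = fnr, npv = npv, fdr = fdr,
    f1 = f1, mcc = mcc
  )
  attr(out, "flags") <- unique(flags)
  out
}

#' Flags of degenerate-denominator metrics
#'
#' @param report A tibble from [compute_metrics()].
#' @return Character vector of flagged metric names.
#' @export
metric_flags <- function(report) {
  f <- attr(report, "flags")
  if (is.null(f)) character(0) else f
}

#' Compare a predicted mask with ground truth
#'
#' Convenience wrapper: [confusion_counts()] then [compute_metrics()].
#'
#' @param y_true,y_pred Binary masks or 0/1 vectors of identical shape.
#' @return One-row metrics tibble.
#' @export
evaluate_masks <- function(y_true, y_pred) {
  compute_metrics(confusion_counts(y_true, y_pred))
}

#' Symmetric volume difference from a Dice score
#'
#' @param dsc Dice similarity coefficient(s).
#' @return `1 - dsc`.
#' @export
svd_from_dsc <- function(dsc) 1 - dsc

#' Dice coefficient of two masks
#'
#' @inheritParams confusion_counts
#' @return Scalar Dice score (1 when both masks are empty).
#' @export
dice <- function(y_true, y_pred) {
  evaluate_masks(y_true, y_pred)$dsc
}
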