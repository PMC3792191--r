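#' Confusion counts with SNO as the positive class
#'
#' @param truth,predicted Character vectors of labels in `{"SNO", "non-SNO"}`,
#'   equal length.
#' @return An object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    sno_error("snopair_validation_error",
              sprintf("truth (%d) and predicted (%d) differ in length",
                      length(truth), length(predicted)))
  ok <- c("SNO", "non-SNO")
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    sno_error("snopair_validation_error",
              "labels must be 'SNO' or 'non-SNO'")
  structure(list(tp = sum(truth == "SNO" & predicted == "SNO"),
                 tn = sum(truth == "non-SNO" & predicted == "non-SNO"),
                 fp = sum(truth == "non-SNO" & predicted == "SNO"),
                 fn = sum(truth == "SNO" & predicted == "non-SNO")),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total, and the Matthews
#' correlation coefficient. Degenerate cases: with no positives evaluated Sn
#' is `NA` (missing, not zero), likewise Sp with no negatives; an MCC whose
#' denominator has an empty marginal is reported as 0 with
#' `mcc_degenerate = TRUE`.
#'
#' @param counts A [confusion_counts()] object (or list with tp/tn/fp/fn).
#' @return An object of class `sno_metrics`: `sn`, `sp`, `acc`, `mcc`,
#'   `mcc_degenerate`, `counts`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0L)
    sno_error("snopair_empty_dataset", "metrics undefined on empty counts")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 mcc_degenerate = degenerate, counts = counts),
            class = "sno_metrics")
}

#' Metrics in error-fraction (Chou-symbol) form
#'
#' The same four metrics written in terms of the class sizes and the two
#' error counts: N+ = TP+FN and its miscalls N+_- = FN, N- = TN+FP and its
#' miscalls N-_+ = FP. Algebraically identical to
#' [classification_metrics()]; kept as an independent formulation and used to
#' cross-check the conventional one.
#'
#' @inheritParams classification_metrics
#' @return Named numeric vector with `sn`, `sp`, `acc`, `mcc`.
#' @export
metrics_chou <- function(counts) {
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  miss_pos <- counts$fn   # SNO predicted non-SNO
  miss_neg <- counts$fp   # non-SNO predicted SNO
  sn <- if (n_pos > 0) 1 - miss_pos / n_pos else NA_real_
  sp <- if (n_neg > 0) 1 - miss_neg / n_neg else NA_real_
  acc <- 1 - (miss_pos + miss_neg) / (n_pos + n_neg)
  den <- (1 + (miss_neg - miss_pos) / n_pos) * (1 + (miss_pos - miss_neg) / n_neg)
  mcc <- if (n_pos == 0 || n_neg == 0 || den <= 0) NA_real_
         else (1 - (miss_pos / n_pos + miss_neg / n_neg)) / sqrt(den)
  c(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' @export
print.sno_metrics <- function(x, digits = 1, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.*f%%", digits, 100 * v)
  cat(sprintf("Sn = %s  Sp = %s  Acc = %s  MCC = %.4f%s\n",
              fmt(x$sn), fmt(x$sp), fmt(x$acc), x$mcc,
              if (x$mcc_degenerate) " (degenerate marginal)" else ""))
  cat(sprintf("  (TP %d, TN %d, FP %d, FN %d)\n",
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  invisible(x)
}

#' One-row data frame form of a metrics report
#'
#' @param x An `sno_metrics` object.
#' @param ... Unused.
#' @return Data frame with columns sn, sp, acc, mcc, tp, tn, fp, fn.
#' @export
as.data.frame.sno_metrics <- function(x, ...) {
  data.frame(sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc,
             tp = x$counts$tp, tn = x$counts$tn,
             fp = x$counts$fp, fn = x$counts$fn)
}
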