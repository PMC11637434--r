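#' Locus-level confusion counts
#'
#' @param predicted Character or logical vector of predicted labels
#'   (`"MSI"`/`TRUE` = positive); NA entries are dropped together with
#'   their truth.
#' @param truth Parallel vector of true labels.
#' @return Object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  to_l <- function(v) if (is.logical(v)) v else v == "MSI"
  p <- to_l(predicted); t <- to_l(truth)
  keep <- !is.na(p) & !is.na(t)
  p <- p[keep]; t <- t[keep]
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy, precision, recall, Matthews correlation coefficient and gain.
#' Gain is defined as `(TP - FP) / (TP + FN)`: the excess of true over
#' false positives relative to the size of the positive class, so it is
#' negative when false positives outnumber true positives. Metrics with an
#' undefined denominator are NA.
#'
#' @param counts A [confusion_counts], or TP when the four counts are given
#'   separately.
#' @param FP,TN,FN Optional separate counts.
#' @return List with `Acc`, `Pre`, `Rec`, `MCC`, `Gain`.
#' @export
compute_metrics <- function(counts, FP = NULL, TN = NULL, FN = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(list(TP = counts, FP = FP, TN = TN, FN = FN),
                        class = "confusion_counts")
  }
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- sdiv(TP + TN, TP + TN + FP + FN)
  pre <- sdiv(TP, TP + FP)
  rec <- sdiv(TP, TP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_
  gain <- sdiv(TP - FP, TP + FN)
  list(Acc = acc, Pre = pre, Rec = rec, MCC = mcc, Gain = gain)
}

#' Reconstruct confusion counts from printed metrics
#'
#' Exhaustively sweeps integer confusion matrices with fixed class sizes
#' (`TP + FN = positives`, `TN + FP = negatives`) and returns those whose
#' metrics, rounded to `digits` decimals, reproduce every supplied value.
#' Useful to validate metric formulas against published benchmark tables.
#'
#' @param Acc,Pre,Rec,MCC,Gain Printed metric values; any may be NA to
#'   leave it unconstrained.
#' @param positives,negatives Class sizes (default 30/30).
#' @param tol Absolute tolerance against the printed (3-decimal) values.
#'   The default 6e-4 accepts both rounding and truncation to 3 decimals,
#'   which published tables mix (the same matrix can appear as 0.904 in
#'   one table and 0.905 in another).
#' @return Data frame of matching `TP`, `FP`, `TN`, `FN` rows (possibly
#'   empty).
#' @export
reconstruct_confusion <- function(Acc = NA, Pre = NA, Rec = NA, MCC = NA,
                                  Gain = NA, positives = 30, negatives = 30,
                                  tol = 6e-4) {
  want <- c(Acc = Acc, Pre = Pre, Rec = Rec, MCC = MCC, Gain = Gain)
  hits <- list()
  for (TP in 0:positives) for (FP in 0:negatives) {
    m <- compute_metrics(TP, FP, negatives - FP, positives - TP)
    got <- unlist(m)
    ok <- TRUE
    for (nm in names(want)) {
      if (!is.na(want[[nm]])) {
        if (is.na(got[[nm]]) || abs(got[[nm]] - want[[nm]]) > tol) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      hits[[length(hits) + 1L]] <- data.frame(TP = TP, FP = FP,
                                              TN = negatives - FP,
                                              FN = positives - TP)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(TP = integer(0), FP = integer(0),
                      TN = integer(0), FN = integer(0)))
  }
  do.call(rbind, hits)
}
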