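# Confusion-count bookkeeping and the enhancement metric suite, with
# lesion = positive.  All derived metrics use the standard closed forms;
# any zero denominator maps to 0 by convention (documented, and never
# exercised by the printed reference counts).

#' Pixelwise confusion counts
#'
#' @param pred_mask,true_mask binary (logical or 0/1) matrices of equal
#'   shape; lesion pixels are the positive class.
#' @return list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("mask shapes must match")
  }
  p <- as.logical(pred_mask); t_ <- as.logical(true_mask)
  structure(list(TP = sum(p & t_), TN = sum(!p & !t_),
                 FP = sum(p & !t_), FN = sum(!p & t_)),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Enhancement metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' (true-positive rate) `TP/(TP+FN)`, false-positive rate `FP/(FP+TN)`,
#' F value `2PR/(P+R)`, Jaccard index `TP/(TP+FP+FN)`, and the Matthews
#' correlation coefficient
#' `(TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Zero denominators yield 0.
#'
#' @param counts a [confusion_counts()] object or list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @return named list with `accuracy`, `precision`, `recall`, `fp_rate`,
#'   `f_value`, `jaccard`, `mcc`.
#' @export
metrics_from_counts <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  total <- TP + TN + FP + FN
  if (total == 0) stop("counts sum to zero")
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(
    accuracy = (TP + TN) / total,
    precision = precision,
    recall = recall,
    fp_rate = safe_div(FP, FP + TN),
    f_value = safe_div(2 * precision * recall, precision + recall),
    jaccard = safe_div(TP, TP + FP + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  )
}

#' Stage-classification report
#'
#' One-vs-rest sensitivity and specificity per stage, plus overall and
#' macro-averaged accuracy.
#'
#' @param preds,labels character vectors of equal length with values in
#'   [stage_levels()] (or any shared class vocabulary).
#' @param classes class vocabulary (default [stage_levels()]).
#' @return list with `overall_accuracy`, `per_class` (data frame with
#'   `class`, `sensitivity`, `specificity`, `n`), `macro_sensitivity`,
#'   `macro_specificity`.
#' @export
stage_report <- function(preds, labels, classes = stage_levels()) {
  if (length(preds) != length(labels)) stop("preds/labels length mismatch")
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop("labels outside the class set: ",
                        paste(bad, collapse = ", "))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(preds == cl & labels == cl)
    fn <- sum(preds != cl & labels == cl)
    fp <- sum(preds == cl & labels != cl)
    tn <- sum(preds != cl & labels != cl)
    data.frame(class = cl,
               sensitivity = safe_div(tp, tp + fn),
               specificity = safe_div(tn, tn + fp),
               n = sum(labels == cl))
  }))
  list(overall_accuracy = mean(preds == labels),
       per_class = per,
       macro_sensitivity = mean(per$sensitivity),
       macro_specificity = mean(per$specificity))
}
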