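## evaluation: ROC / PRC curves and areas, nearest-top-left threshold
## selection, confusion-matrix metrics, and the MLO evaluation protocol.

check_binary <- function(labels) {
  l <- as.logical(labels)
  if (anyNA(l)) stop("labels must be logical or 0/1")
  if (length(unique(l)) < 2) stop("both classes must be present")
  l
}

#' ROC and precision-recall curves with areas
#'
#' Scores are grouped at ties; AUROC is the trapezoidal area under the
#' ROC curve and AUPRC the step-wise (average-precision) integration of
#' the precision-recall curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 truth.
#' @return List with `roc` (threshold, fpr, tpr), `prc` (threshold,
#'   recall, precision), `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
roc_prc <- function(scores, labels) {
  labels <- check_binary(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  np <- sum(labels); nn <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)  # last row of each tie group
  thr <- s[last]
  tpr <- tp[last] / np
  fpr <- fp[last] / nn
  rec <- tpr
  prec <- tp[last] / (tp[last] + fp[last])
  auroc <- sum(diff(c(0, fpr)) * (tpr + c(0, utils::head(tpr, -1)))) / 2
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       prc = data.frame(threshold = thr, recall = rec, precision = prec),
       auroc = auroc, auprc = auprc, n_pos = np, n_neg = nn)
}

#' Area under the ROC curve
#' @inheritParams roc_prc
#' @return Scalar AUROC.
#' @export
auroc <- function(scores, labels) roc_prc(scores, labels)$auroc

#' Area under the precision-recall curve
#' @inheritParams roc_prc
#' @return Scalar AUPRC.
#' @export
auprc <- function(scores, labels) roc_prc(scores, labels)$auprc

#' Nearest-top-left-corner score threshold
#'
#' Returns the threshold of the ROC point minimising
#' sqrt(FPR^2 + (1 - TPR)^2); ties resolve to the higher-specificity
#' (lower FPR) point. Scores at or above the threshold predict positive.
#'
#' @param roc data.frame with `threshold`, `fpr`, `tpr` (from
#'   [roc_prc()]), or the full `roc_prc` result.
#' @return Scalar threshold.
#' @export
select_threshold <- function(roc) {
  if (!is.data.frame(roc)) roc <- roc$roc
  d <- roc$fpr^2 + (1 - roc$tpr)^2
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(roc$fpr[best])]
  roc$threshold[best]
}

#' Confusion-matrix metrics at a threshold
#'
#' Positive prediction is `score >= threshold` (inclusive). MCC is 0 when
#' any marginal factor is 0.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 truth.
#' @param threshold decision threshold.
#' @return List of class `metrics_report`: auroc, auprc, threshold, mcc,
#'   f1, sensitivity, specificity, accuracy, fpr, fnr, n_pos, n_neg.
#' @export
binary_metrics <- function(scores, labels, threshold) {
  labels <- check_binary(labels)
  stopifnot(is.finite(threshold))
  pred <- scores >= threshold
  tp <- sum(pred & labels);  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  rp <- roc_prc(scores, labels)
  structure(list(auroc = rp$auroc, auprc = rp$auprc, threshold = threshold,
                 mcc = mcc, f1 = f1, sensitivity = sens, specificity = spec,
                 accuracy = acc, fpr = 1 - spec, fnr = 1 - sens,
                 n_pos = rp$n_pos, n_neg = rp$n_neg),
            class = "metrics_report")
}

#' MLO-set evaluation protocol
#'
#' Membraneless-organelle membership is a weak positive label: positives
#' are the MLO proteins minus the positive training set, split into ID
#' and noID classes by the pipeline's own IDR call; negatives are the
#' negative testing set. AUROC/AUPRC are reported per class, `NA` when a
#' class is empty after the exclusion.
#'
#' @param mlo_ids identifiers in the MLO dataset.
#' @param training_positive_ids identifiers to exclude.
#' @param negative_test_ids identifiers of the negative testing set.
#' @param scores named numeric vector of prediction scores by id.
#' @param idr_class named character vector ("ID"/"noID") by id.
#' @return List with `ID` and `noID` components, each either a list
#'   (auroc, auprc, n_pos, n_neg) or NULL when undefined.
#' @export
mlo_protocol <- function(mlo_ids, training_positive_ids, negative_test_ids,
                         scores, idr_class) {
  pos <- setdiff(mlo_ids, training_positive_ids)
  neg <- setdiff(negative_test_ids, pos)
  out <- list(ID = NULL, noID = NULL)
  for (cls in c("ID", "noID")) {
    p <- pos[idr_class[pos] == cls & !is.na(idr_class[pos])]
    p <- intersect(p, names(scores))
    n <- intersect(neg, names(scores))
    if (!length(p) || !length(n)) next
    s <- c(scores[p], scores[n])
    l <- c(rep(TRUE, length(p)), rep(FALSE, length(n)))
    rp <- roc_prc(s, l)
    out[[cls]] <- list(auroc = rp$auroc, auprc = rp$auprc,
                       n_pos = length(p), n_neg = length(n))
  }
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("AUROC %.3f  AUPRC %.3f  thr %.3f\nMCC %.3f  F1 %.3f  ",
           "sens %.3f  spec %.3f  acc %.3f  FPR %.3f  FNR %.3f  ",
           "(%d pos / %d neg)\n"),
    x$auroc, x$auprc, x$threshold, x$mcc, x$f1, x$sensitivity,
    x$specificity, x$accuracy, x$fpr, x$fnr, x$n_pos, x$n_neg))
  invisible(x)
}
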