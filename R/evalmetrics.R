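# Confusion-matrix statistics and ROC/AUC.
#
# SE = TP/(TP+FN), SP = TN/(TN+FP), Q = (TP+TN)/total (SE, SP, Q reported
# in percent), and the Matthews correlation coefficient with the standard
# denominator sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

#' Confusion matrix from predicted and true labels
#'
#' @param preds predicted labels in `{+1, -1}`.
#' @param truth true labels in `{+1, -1}`.
#' @return object of class `confusion_matrix` with fields TP, FN, TN, FP.
#' @export
confusion <- function(preds, truth) {
  preds <- as.integer(preds); truth <- as.integer(truth)
  if (length(preds) != length(truth)) stop("length mismatch")
  if (!all(c(preds, truth) %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  structure(list(TP = sum(preds == 1L & truth == 1L),
                 FN = sum(preds == -1L & truth == 1L),
                 TN = sum(preds == -1L & truth == -1L),
                 FP = sum(preds == 1L & truth == -1L)),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param TP,FN,TN,FP cell counts.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FN=%d TN=%d FP=%d>\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Sensitivity, specificity, total accuracy and MCC
#'
#' `se`, `sp` and `q_total` are percentages; `mcc` lies in `[-1, 1]`. A zero
#' marginal makes the statistic undefined: `NA` is returned with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return numeric scalar.
#' @export
se <- function(cm) {
  if (cm$TP + cm$FN == 0) { warning("no actual positives; SE undefined"); return(NA_real_) }
  100 * cm$TP / (cm$TP + cm$FN)
}

#' @rdname se
#' @export
sp <- function(cm) {
  if (cm$TN + cm$FP == 0) { warning("no actual negatives; SP undefined"); return(NA_real_) }
  100 * cm$TN / (cm$TN + cm$FP)
}

#' @rdname se
#' @export
q_total <- function(cm) {
  n <- cm$TP + cm$FN + cm$TN + cm$FP
  if (n == 0) { warning("empty confusion matrix; Q undefined"); return(NA_real_) }
  100 * (cm$TP + cm$TN) / n
}

#' @rdname se
#' @export
mcc <- function(cm) {
  den <- (cm$TP + cm$FP) * (cm$TP + cm$FN) * (cm$TN + cm$FP) * (cm$TN + cm$FN)
  if (den == 0) { warning("zero marginal; MCC undefined"); return(NA_real_) }
  (cm$TP * cm$TN - cm$FN * cm$FP) / sqrt(den)
}

#' All four statistics at the conventional printed precision
#'
#' @param cm a `confusion_matrix`.
#' @param digits decimal places (half-up rounding, 2 as conventionally
#'   printed).
#' @return named numeric vector `SE`, `SP`, `Q`, `MCC` (MCC to
#'   `digits + 2`).
#' @export
classification_metrics <- function(cm, digits = 2L) {
  half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  c(SE = half_up(se(cm), digits), SP = half_up(sp(cm), digits),
    Q = half_up(q_total(cm), digits), MCC = half_up(mcc(cm), digits + 2L))
}

#' ROC curve
#'
#' Sweeps a decision threshold over the unique scores in descending order;
#' each threshold contributes the point (1 - SP, SE). Tied scores are
#' processed as a single threshold step, which makes the trapezoidal area
#' equal to the Mann-Whitney statistic with half-credit for ties.
#'
#' @param scores numeric prediction scores (larger = more active).
#' @param truth labels in `{+1, -1}`; both classes must be present.
#' @return object of class `roc_curve`: data.frame with columns `fpr`
#'   (1 - SP) and `tpr` (SE), plus an `auc` attribute.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) stop("ROC needs both classes in truth")
  np <- sum(truth == 1L); nn <- sum(truth == -1L)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  fpr <- 0; tpr <- 0; cp <- 0L; cn <- 0L
  i <- 1L; n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    cp <- cp + sum(t[i:j] == 1L); cn <- cn + sum(t[i:j] == -1L)
    fpr <- c(fpr, cn / nn); tpr <- c(tpr, cp / np)
    i <- j + 1L
  }
  curve <- data.frame(fpr = fpr, tpr = tpr)
  a <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(curve, class = c("roc_curve", "data.frame"), auc = a)
}

#' Area under a ROC curve
#'
#' Trapezoidal area; with the tie handling of [roc_curve()] this equals the
#' Mann-Whitney pair statistic with half-credit for score ties.
#'
#' @param curve a `roc_curve` (or numeric scores with `truth` supplied).
#' @param truth optional labels, to compute directly from scores.
#' @return numeric in `[0, 1]`.
#' @export
auc <- function(curve, truth = NULL) {
  if (!is.null(truth)) curve <- roc_curve(curve, truth)
  attr(curve, "auc")
}

#' Write an evaluation report
#'
#' @param cm a `confusion_matrix`.
#' @param roc optional `roc_curve`; adds AUC and writes the curve points.
#' @param path output path; `.json` or `.csv` chosen by extension.
#' @return invisibly, the path.
#' @export
write_metrics_report <- function(cm, roc = NULL, path) {
  m <- as.list(classification_metrics(cm))
  m <- c(list(TP = cm$TP, FN = cm$FN, TN = cm$TN, FP = cm$FP), m)
  if (!is.null(roc)) m$AUC <- attr(roc, "auc")
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  }
  if (!is.null(roc))
    utils::write.csv(as.data.frame(roc),
                     sub("\\.(json|csv)$", "_roc.csv", path), row.names = FALSE)
  invisible(path)
}
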