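# Evaluation metrics: confusion counts, sensitivity/specificity/accuracy/PPV
# and ROC/AUC by threshold variation, for the 7-way multilabel task and the
# binary BCC diagnosis.

#' Confusion counts
#'
#' @param y_true,y_pred Logical (or 0/1) vectors of equal length.
#' @return A `confusion_counts` object with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.logical(y_true)
  y_pred <- as.logical(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred must align")
  if (length(y_true) < 1L) stop("empty input")
  structure(list(tp = sum(y_pred & y_true),
                 fp = sum(y_pred & !y_true),
                 tn = sum(!y_pred & !y_true),
                 fn = sum(!y_pred & y_true)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' sens = tp / (tp + fn), spec = tn / (tn + fp), acc = (tp + tn) / total,
#' ppv = tp / (tp + fp). A zero denominator raises an error rather than
#' returning a silent 0 (which would corrupt macro averages over rare
#' patterns).
#'
#' @param c A `confusion_counts` object.
#' @param which Metrics to compute (default all four).
#' @return Named numeric vector.
#' @export
metrics_from_counts <- function(c,
                                which = c("sensitivity", "specificity",
                                          "accuracy", "ppv")) {
  stopifnot(inherits(c, "confusion_counts"))
  which <- match.arg(which, several.ok = TRUE)
  safe <- function(num, den, name) {
    if (den == 0) stop(sprintf("%s is undefined: zero denominator", name))
    num / den
  }
  out <- c()
  if ("sensitivity" %in% which) out["sensitivity"] <- safe(c$tp, c$tp + c$fn, "sensitivity")
  if ("specificity" %in% which) out["specificity"] <- safe(c$tn, c$tn + c$fp, "specificity")
  if ("accuracy" %in% which) out["accuracy"] <- safe(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")
  if ("ppv" %in% which) out["ppv"] <- safe(c$tp, c$tp + c$fp, "ppv")
  out
}

#' ROC curve and AUC by threshold variation
#'
#' Sweeps the detection threshold over the observed scores, grouping tied
#' scores, and integrates the empirical ROC by the trapezoidal rule
#' (equivalent to the Mann-Whitney statistic with ties counted one half).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y_true Logical (or 0/1) truth; both classes must be present.
#' @return List with `auc` and `roc`, a data frame of `(fpr, tpr)` points
#'   running from (0, 0) to (1, 1) with both coordinates non-decreasing.
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- as.logical(y_true)
  if (length(scores) != length(y_true)) stop("scores and y_true must align")
  if (length(unique(y_true)) < 2L) {
    stop("ROC is undefined when only one class is present")
  }
  r <- pROC::roc(response = y_true, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  roc <- data.frame(fpr = (1 - r$specificities)[ord],
                    tpr = r$sensitivities[ord])
  list(auc = as.numeric(pROC::auc(r)), roc = roc)
}

#' Per-pattern and macro-averaged multilabel report
#'
#' Computes sensitivity, specificity, accuracy, PPV and AUC per dermoscopic
#' pattern, plus their unweighted macro means.
#'
#' @param probs n x 7 probability matrix.
#' @param labels n x 7 binary label matrix ([bcc_patterns()] order).
#' @param thresholds Detection thresholds (see [apply_thresholds()]).
#' @return List with `per_pattern` (data frame, one row per pattern) and
#'   `macro` (named means over patterns).
#' @export
multilabel_report <- function(probs, labels, thresholds = 0.5) {
  y <- .as_label_matrix(labels)
  if (!all(dim(probs) == dim(y))) stop("probs and labels must be n x 7 and aligned")
  if (is.null(colnames(probs))) colnames(probs) <- bcc_patterns()
  probs <- probs[, bcc_patterns(), drop = FALSE]
  d <- apply_thresholds(probs, thresholds)
  rows <- lapply(bcc_patterns(), function(k) {
    cc <- confusion(y[, k] == 1, d[, k])
    m <- metrics_from_counts(cc)
    auc <- roc_auc(probs[, k], y[, k] == 1)$auc
    data.frame(pattern = k, sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], accuracy = m[["accuracy"]],
               ppv = m[["ppv"]], auc = auc)
  })
  per <- do.call(rbind, rows)
  macro <- colMeans(per[, -1L])
  list(per_pattern = per, macro = macro)
}

#' Binary BCC diagnosis report
#'
#' @param y_true Logical truth (TRUE = BCC).
#' @param y_pred Logical prediction, or the `"BCC"`/`"nonBCC"` labels of
#'   [bcc_rule()].
#' @return Named metrics vector plus the confusion counts as an attribute.
#' @export
binary_report <- function(y_true, y_pred) {
  if (is.character(y_pred)) y_pred <- y_pred == "BCC"
  if (is.character(y_true)) y_true <- y_true == "BCC"
  cc <- confusion(y_true, y_pred)
  m <- metrics_from_counts(cc)
  attr(m, "counts") <- cc
  m
}
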