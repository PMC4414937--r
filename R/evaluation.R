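# Single-feature classification evaluation.
#
# The malignant class is the positive class throughout. The direction
# convention is "malignant-high": spiculated, irregular lesions score
# higher on every one of the six contour features, so a score at or above
# the threshold is called positive. ROC curves are computed by a full
# threshold sweep; the AUC is the Mann-Whitney two-sample statistic
# (probability that a random malignant case outscores a random benign
# case, ties counting one half).

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' \deqn{Accuracy = \frac{TP+TN}{TP+TN+FP+FN},\quad
#'       Sensitivity = \frac{TP}{TP+FN},\quad
#'       Specificity = \frac{TN}{TN+FP},}
#' returned as percentages. TP counts malignant cases called positive and
#' TN benign cases called negative.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; alternatively `tp` can
#'   be a list/vector with named elements `tp`, `tn`, `fp`, `fn`.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)` in
#'   percent.
#' @export
binary_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (length(tp) == 4 && !is.null(names(tp)))) {
    c0 <- tp
    tp <- c0[["tp"]]; tn <- c0[["tn"]]; fp <- c0[["fp"]]; fn <- c0[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  if (tp + fn == 0) stop("undefined sensitivity: no positive (malignant) cases", call. = FALSE)
  if (tn + fp == 0) stop("undefined specificity: no negative (benign) cases", call. = FALSE)
  c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad) > 0) stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  labels
}

#' Confusion counts at a fixed threshold
#'
#' Malignant-positive convention: with the default `"high"` direction a
#' score `>= threshold` is called positive (ties go to the positive call);
#' with `"low"`, a score `<= threshold` is.
#'
#' @param scores numeric feature values, one per case.
#' @param labels `"benign"`/`"malignant"` per case.
#' @param threshold decision threshold.
#' @param direction which side of the threshold indicates malignancy.
#' @return Named list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
classify_by_threshold <- function(scores, labels, threshold,
                                  direction = c("high", "low")) {
  direction <- match.arg(direction)
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ", call. = FALSE)
  pos <- if (direction == "high") scores >= threshold else scores <= threshold
  mal <- labels == "malignant"
  list(tp = sum(pos & mal), tn = sum(!pos & !mal),
       fp = sum(pos & !mal), fn = sum(!pos & mal))
}

#' ROC curve, AUC and Youden threshold
#'
#' Sweeps every unique score as a candidate threshold (plus one above the
#' maximum for the all-negative operating point) and records the
#' sensitivity/1-specificity pairs. The AUC is computed as the normalized
#' Mann-Whitney statistic: the fraction of (malignant, benign) pairs in
#' which the malignant case scores on the malignant side, ties counting
#' 1/2 — which equals the trapezoidal area under the swept curve. The
#' Youden threshold maximizes sensitivity + specificity - 1; ties are
#' broken toward the lower threshold.
#'
#' @inheritParams classify_by_threshold
#' @return An object of class `hc_roc`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `youden_threshold`, `direction`.
#' @export
roc_auc <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ", call. = FALSE)
  s <- if (direction == "high") scores else -scores
  mal <- labels == "malignant"
  nm <- sum(mal)
  nb <- sum(!mal)
  # Mann-Whitney AUC via midranks
  r <- rank(s)
  auc <- (sum(r[mal]) - nm * (nm + 1) / 2) / (nm * nb)
  thr <- sort(unique(s))
  thr <- c(thr, max(thr) + 1)  # all-negative endpoint
  tpr <- vapply(thr, function(t) sum(s[mal] >= t) / nm, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!mal] >= t) / nb, numeric(1))
  j <- tpr - fpr
  best <- which(j == max(j))
  youden <- thr[min(best)]  # lowest threshold among ties
  out <- list(
    thresholds = if (direction == "high") thr else -thr,
    tpr = tpr, fpr = fpr, auc = auc,
    youden_threshold = if (direction == "high") youden else -youden,
    direction = direction
  )
  class(out) <- "hc_roc"
  out
}

#' @export
print.hc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d thresholds; Youden threshold = %.4g (direction: %s)\n",
              x$auc, length(x$thresholds), x$youden_threshold, x$direction))
  invisible(x)
}

#' @export
plot.hc_roc <- function(x, ...) {
  ord <- order(x$fpr, x$tpr)
  graphics::plot(x$fpr[ord], x$tpr[ord], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Two-sided Welch t-test
#'
#' Unequal-variance two-sample t-test via [stats::t.test()]. When both
#' groups are degenerate (zero variance) with equal means the p-value is 1
#' by convention; zero variance with distinct means is an error.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return Named list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("degenerate groups: zero variance with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Evaluate one feature over a labeled cohort
#'
#' Computes the ROC/AUC, the confusion metrics at the Youden threshold
#' (resubstitution: the threshold is chosen on the same sample it is
#' evaluated on, which is optimistic), and the Welch t-test p-value between
#' the benign and malignant groups.
#'
#' @param features data frame with at least the columns `label`, `mode`,
#'   and the feature column, one row per case and mode (as produced by
#'   [run_experiment()] or [as.data.frame.hc_features()]).
#' @param feature feature column name (`"tc"`, `"nrl_m"`, `"nrl_std"`,
#'   `"ar"`, `"ri"` or `"sdd"`).
#' @param mode `"full"` or `"half"`.
#' @param direction threshold direction, default malignant-high.
#' @return One-row data frame: feature, mode, n, accuracy, sensitivity,
#'   specificity (percent), auc, threshold, t, p.
#' @export
evaluate_cohort <- function(features, feature, mode = c("full", "half"),
                            direction = "high") {
  mode <- match.arg(mode)
  if (!feature %in% names(features)) stop("feature column not found: ", feature, call. = FALSE)
  sub <- features[features$mode == mode, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for mode ", mode, call. = FALSE)
  scores <- sub[[feature]]
  if (any(!is.finite(scores))) stop("non-finite feature values for ", feature, call. = FALSE)
  labels <- check_labels(sub$label)
  roc <- roc_auc(scores, labels, direction = direction)
  cc <- classify_by_threshold(scores, labels, roc$youden_threshold,
                              direction = direction)
  bm <- binary_metrics(cc)
  tt <- welch_t_test(scores[labels == "malignant"], scores[labels == "benign"])
  data.frame(feature = feature, mode = mode, n = nrow(sub),
             accuracy = unname(bm["accuracy"]),
             sensitivity = unname(bm["sensitivity"]),
             specificity = unname(bm["specificity"]),
             auc = roc$auc, threshold = roc$youden_threshold,
             t = tt$t, p = tt$p, stringsAsFactors = FALSE)
}

#' Evaluate all features in all modes
#'
#' @param features per-case feature table (see [evaluate_cohort()]).
#' @param feature_names feature columns to evaluate.
#' @param modes contour modes to evaluate.
#' @inheritParams evaluate_cohort
#' @return A data frame of class `hc_report`, one row per feature and mode.
#' @export
evaluate_all <- function(features,
                         feature_names = c("tc", "nrl_m", "nrl_std", "ar", "ri", "sdd"),
                         modes = c("full", "half"), direction = "high") {
  rows <- list()
  for (f in feature_names) {
    for (m in modes) {
      rows[[length(rows) + 1L]] <- evaluate_cohort(features, f, m, direction)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hc_report", class(out))
  out
}

#' @export
print.hc_report <- function(x, digits = 3, ...) {
  cat("Per-feature classification report (Youden threshold, resubstitution):\n")
  df <- as.data.frame(x)
  df$accuracy <- round(df$accuracy, 1)
  df$sensitivity <- round(df$sensitivity, 1)
  df$specificity <- round(df$specificity, 1)
  df$auc <- round(df$auc, digits)
  df$threshold <- signif(df$threshold, digits)
  df$t <- round(df$t, 2)
  df$p <- signif(df$p, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
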