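coerce_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    if (nlevels(f) != 2L) rlang::abort("labels must have exactly 2 levels.")
    return(as.integer(f) - 1L)   # second level = positive class
  }
  if (!all(labels %in% c(0, 1))) rlang::abort("numeric labels must be 0/1.")
  as.integer(labels)
}

#' ROC curve and area under the curve
#'
#' AUC is the Mann–Whitney probability that a random positive outscores a
#' random negative, with ties counted one half. The ROC is the step curve over
#' the unique score thresholds (predict positive when `score >= threshold`).
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, 0/1, or two-level factor whose second
#'   level is the positive class).
#' @return list with `auc` and `roc` (tibble `threshold`, `fpr`, `tpr`),
#'   class `roc_curve`.
#' @export
roc_auc <- function(scores, labels) {
  y <- coerce_binary(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) rlang::abort("both classes must be present.")
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  )
  structure(list(auc = auc, roc = roc), class = "roc_curve")
}

#' Youden-optimal operating threshold
#'
#' Maximizes `J = sensitivity + specificity - 1 = TPR - FPR` along the ROC;
#' ties are broken toward higher sensitivity.
#'
#' @param roc a `roc_curve` from [roc_auc()] or its `roc` tibble.
#' @return list with `threshold` and `j`.
#' @export
youden_threshold <- function(roc) {
  pts <- if (inherits(roc, "roc_curve")) roc$roc else roc
  if (nrow(pts) < 1L) rlang::abort("ROC has no thresholds.")
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[which.max(pts$tpr[best])]
  list(threshold = pts$threshold[best], j = j[best])
}
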