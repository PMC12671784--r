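# Classification metrics and the statistical tests used for model
# comparison: confusion counts at the 0.5 threshold, Acc/Sen/Spe/F1/MCC,
# AUROC (Mann-Whitney normalisation), DeLong's test for correlated ROC
# curves, the Wilcoxon signed-rank test and Cohen's d.

#' Confusion counts at a probability threshold
#'
#' The boundary is inclusive: a score exactly at the threshold is classified
#' positive (preictal).
#'
#' @param scores predicted positive-class probabilities.
#' @param labels 0/1 true labels.
#' @param threshold decision threshold (default 0.5).
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Acc = (TP+TN)/total, Sen = TP/(TP+FN), Spe = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param c a [confusion()] result (or list with TP/TN/FP/FN).
#' @return list with `acc`, `sen`, `spe`, `f1`, `mcc`.
#' @export
compute_metrics <- function(c) {
  tp <- c$TP; tn <- c$TN; fp <- c$FP; fn <- c$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(acc = (tp + tn) / total,
       sen = safe_div(tp, tp + fn),
       spe = safe_div(tn, tn + fp),
       f1 = safe_div(2 * tp, 2 * tp + fp + fn),
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_)
}

#' Area under the ROC curve
#'
#' Mann-Whitney normalisation: the probability that a random positive
#' outscores a random negative, ties counted half.
#'
#' @param scores predicted scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC", call. = FALSE)
  r <- rank(scores)             # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong's test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors for the same samples using the
#' DeLong covariance estimate of the paired difference (two-sided). A
#' degenerate comparison with zero variance of the difference (e.g.
#' identical scores) is reported as p = 1 with `degenerate = TRUE`.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `p`, `degenerate`.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  stopifnot(length(scoresA) == length(scoresB),
            length(scoresA) == length(labels))
  auc_a <- auroc(scoresA, labels)
  auc_b <- auroc(scoresB, labels)
  # DeLong structural components: variance of the paired AUC difference
  placements <- function(s) {
    pos <- s[labels == 1]; neg <- s[labels == 0]
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
    v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), 0)
    list(v10 = v10, v01 = v01)
  }
  pa <- placements(scoresA); pb <- placements(scoresB)
  var_diff <- stats::var(pa$v10 - pb$v10) / length(pa$v10) +
    stats::var(pa$v01 - pb$v01) / length(pa$v01)
  if (!is.finite(var_diff) || var_diff <= 0) {
    return(list(auc_a = auc_a, auc_b = auc_b, p = 1, degenerate = TRUE))
  }
  res <- tryCatch({
    ra <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<")
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- as.numeric(tst$p.value)
    if (!is.finite(p)) list(p = 1, degenerate = TRUE)
    else list(p = p, degenerate = FALSE)
  }, error = function(e) list(p = 1, degenerate = TRUE))
  list(auc_a = auc_a, auc_b = auc_b, p = res$p, degenerate = res$degenerate)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Accepts a vector of paired differences or a two-column matrix. Zero
#' differences are discarded; the p-value is exact (by enumeration of sign
#' assignments) for n <= 25 without ties, and uses the normal approximation
#' beyond.
#'
#' @param pairs numeric vector of differences, or a two-column matrix whose
#'   difference `[,1] - [,2]` is tested.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(pairs) {
  d <- if (is.matrix(pairs)) pairs[, 1] - pairs[, 2] else as.numeric(pairs)
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero: test undefined", call. = FALSE)
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    return(suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value))
  }
  if (n <= 14 && ties) {
    # exact by enumerating all 2^n sign assignments (average ranks for ties)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- as.numeric(signs %*% r)
    return(min(1, 2 * min(mean(w <= obs), mean(w >= obs))))
  }
  suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
}

#' Cohen's d effect size
#'
#' Mean difference over the pooled standard deviation.
#'
#' @param groupA,groupB numeric vectors (each of size >= 2).
#' @return Cohen's d (positive when groupA has the larger mean).
#' @export
cohens_d <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(groupA) - mean(groupB)) / sp
}
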