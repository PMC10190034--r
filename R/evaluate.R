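# Precision-recall machinery, auPRC/auROC, threshold selection and
# region-stratified evaluation.

#' Precision-recall curve
#'
#' One point per distinct score, swept from the highest threshold down; a
#' variant is called splice-altering when `score >= threshold`, so tied
#' scores share a threshold. auPRC uses step-wise (rectangular)
#' integration over recall, with the precision at recall 0 anchored to the
#' precision of the top-ranked point (PR interpolation conventions differ;
#' this one is documented and exactly recomputable).
#'
#' @param scores numeric scores (no `NA`).
#' @param labels logical (or `positive`/`negative`) truth labels; both
#'   classes must be present.
#' @return object of class `pr_curve`: `points` (threshold, tp, fp, fn, tn,
#'   precision, recall, specificity), `auprc`, `n_pos`, `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  y <- label_to_logical(labels)
  if (anyNA(scores) || anyNA(y)) stop("scores and labels must not contain NA")
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes are required to build a PR curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  cum_tp <- cumsum(yo); cum_fp <- cumsum(!yo)
  # counts at the *last* occurrence of each threshold value (ties share one)
  last_idx <- length(s) - match(thr, rev(s)) + 1L
  tp <- cum_tp[last_idx]; fp <- cum_fp[last_idx]
  fn <- n_pos - tp; tn <- n_neg - fp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  points <- data.frame(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
                       precision = precision, recall = recall,
                       specificity = tn / n_neg)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(points = points, auprc = auprc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pr_curve")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) auROC; tied scores contribute 1/2.
#'
#' @inheritParams pr_curve
#' @return numeric scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- label_to_logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for auROC")
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F1-optimal threshold
#'
#' Maximises F1 = 2PR/(P+R) over the curve's points; ties break toward the
#' higher threshold (higher specificity).
#'
#' @param curve a [pr_curve()].
#' @return list: `threshold`, `f1`, `sensitivity`, `specificity`.
#' @export
f1_optimal_threshold <- function(curve) {
  p <- curve$points
  f1 <- ifelse(p$precision + p$recall > 0,
               2 * p$precision * p$recall / (p$precision + p$recall), 0)
  best <- which(f1 >= max(f1) - 1e-12)[1L]  # points sorted by decreasing thr
  list(threshold = p$threshold[best], f1 = f1[best],
       sensitivity = p$recall[best], specificity = p$specificity[best])
}

#' Threshold achieving a target precision
#'
#' Lowest threshold whose precision is at least `target`; `NA` when the
#' target is unattainable anywhere on the curve (such a tool would be
#' excluded from downstream comparisons).
#'
#' @param curve a [pr_curve()].
#' @param target precision target in (0, 1] (default 0.95).
#' @return numeric threshold or `NA_real_`.
#' @export
threshold_at_precision <- function(curve, target = 0.95) {
  if (target <= 0 || target > 1) stop("target precision must be in (0, 1]")
  p <- curve$points
  ok <- which(p$precision >= target)
  if (!length(ok)) return(NA_real_)
  min(p$threshold[ok])
}

#' Threshold achieving a target specificity
#'
#' Lowest threshold with specificity at least `target`, reported with its
#' paired sensitivity; when no point attains the target the highest
#' threshold (most specific available operating point) is returned.
#'
#' @param curve a [pr_curve()].
#' @param target specificity target in (0, 1].
#' @return list: `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_at_specificity <- function(curve, target) {
  p <- curve$points
  ok <- which(p$specificity >= target)
  best <- if (length(ok)) ok[which.min(p$threshold[ok])] else 1L
  list(threshold = p$threshold[best], sensitivity = p$recall[best],
       specificity = p$specificity[best])
}

#' Threshold achieving a target sensitivity
#'
#' The reverse search direction: highest threshold with sensitivity at
#' least `target`, with its paired specificity (used when calibrating to a
#' sensitivity level rather than a specificity level).
#'
#' @param curve a [pr_curve()].
#' @param target sensitivity target in (0, 1].
#' @return list: `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_at_sensitivity <- function(curve, target) {
  p <- curve$points
  ok <- which(p$recall >= target)
  best <- if (length(ok)) ok[which.max(p$threshold[ok])] else nrow(p)
  list(threshold = p$threshold[best], sensitivity = p$recall[best],
       specificity = p$specificity[best])
}

#' Region-stratified recall
#'
#' Recall within each region class (donor/acceptor/exon/intron) at a given
#' calling threshold. Strata without positives are reported as `NA`
#' (undefined), not 0.
#'
#' @param scores,labels as in [pr_curve()].
#' @param regions region class per variant.
#' @param threshold calling threshold (call iff `score >= threshold`).
#' @return data.frame: region, n_pos, n_called, recall.
#' @export
stratified_recall <- function(scores, labels, regions, threshold) {
  y <- label_to_logical(labels)
  out <- lapply(sort(unique(regions)), function(r) {
    in_r <- regions == r & y
    data.frame(region = r, n_pos = sum(in_r),
               n_called = sum(in_r & scores >= threshold),
               recall = if (sum(in_r)) mean(scores[in_r] >= threshold)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Concordance between two scoring tools
#'
#' 2x2 agreement of the binary calls of two tools at their respective
#' thresholds on the same variants, plus the discordant variants and each
#' tool's false positives.
#'
#' @param scores_a,scores_b named numeric vectors over identical variant
#'   keys (a key mismatch is an error).
#' @param labels truth labels in the same order as `scores_a`.
#' @param threshold_a,threshold_b per-tool calling thresholds.
#' @return list: `concordant_fraction`, `discordant` (data.frame id,
#'   score_a, score_b, label), `false_positives_a`, `false_positives_b`.
#' @export
concordance <- function(scores_a, scores_b, labels, threshold_a, threshold_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b)) ||
      !identical(sort(names(scores_a)), sort(names(scores_b))))
    stop("scores_a and scores_b must be named over the same variant keys")
  scores_b <- scores_b[names(scores_a)]
  y <- label_to_logical(labels)
  call_a <- scores_a >= threshold_a
  call_b <- scores_b >= threshold_b
  disc <- which(call_a != call_b)
  list(concordant_fraction = mean(call_a == call_b),
       discordant = data.frame(id = names(scores_a)[disc],
                               score_a = unname(scores_a[disc]),
                               score_b = unname(scores_b[disc]),
                               label = y[disc], stringsAsFactors = FALSE),
       false_positives_a = sum(call_a & !y),
       false_positives_b = sum(call_b & !y))
}
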