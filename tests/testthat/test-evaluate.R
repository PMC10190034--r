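# Precision-recall machinery and threshold calibration.

random_case <- function(n = 30, tie_prob = 0.5) {
  scores <- stats::runif(n)
  if (stats::runif(1) < tie_prob) scores <- round(scores, 1)  # force ties
  labels <- stats::runif(n) < 0.4
  while (!any(labels) || all(labels)) labels <- stats::runif(n) < 0.4
  list(scores = scores, labels = labels)
}

test_that("PR curve handles perfect and constant classifiers", {
  curve <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(curve$auprc, 1)
  expect_equal(threshold_at_precision(curve), 0.8)
  f1 <- f1_optimal_threshold(curve)
  expect_equal(f1$f1, 1)
  expect_equal(f1$threshold, 0.8)
  # constant scores: one point, precision = prevalence
  cc <- pr_curve(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(nrow(cc$points), 1L)
  expect_equal(cc$points$precision, 0.3)
  expect_equal(f1_optimal_threshold(cc)$threshold, 0.5)
  expect_error(pr_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # an all-wrong classifier cannot reach precision 0.95
  aw <- pr_curve(c(0.9, 0.8, 0.1, 0.05), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(is.na(threshold_at_precision(aw, 0.95)))
})

test_that("PR machinery matches the enumerate-all-thresholds oracle", {
  set.seed(81)
  for (i in 1:100) {
    cs <- random_case()
    curve <- pr_curve(cs$scores, cs$labels)
    ref <- oracle_pr(cs$scores, cs$labels)
    expect_equal(curve$auprc, ref$auprc, tolerance = 1e-12, info = i)
    expect_equal(curve$points$precision, ref$points$precision, info = i)
    expect_equal(curve$points$recall, ref$points$recall, info = i)
    f1 <- f1_optimal_threshold(curve)
    expect_equal(f1$threshold, ref$f1_threshold, info = i)
    expect_equal(f1$sensitivity, ref$f1_sensitivity, info = i)
    expect_equal(f1$specificity, ref$f1_specificity, info = i)
    expect_equal(threshold_at_precision(curve, 0.95), ref$thr_at_p95, info = i)
    for (target in c(0.6, 0.9)) {
      expect_equal(threshold_at_specificity(curve, target)$threshold,
                   ref$thr_at_spec(target), info = paste(i, target))
    }
  }
})

test_that("auPRC is invariant under strictly monotone score transforms", {
  set.seed(82)
  for (i in 1:20) {
    cs <- random_case()
    a1 <- pr_curve(cs$scores, cs$labels)$auprc
    expect_equal(pr_curve(2 * cs$scores + 1, cs$labels)$auprc, a1,
                 tolerance = 1e-12)
    expect_equal(pr_curve(stats::plogis(3 * cs$scores), cs$labels)$auprc, a1,
                 tolerance = 1e-12)
  }
})

test_that("threshold_at_precision is monotone in the target", {
  set.seed(83)
  for (i in 1:20) {
    cs <- random_case()
    curve <- pr_curve(cs$scores, cs$labels)
    prev <- -Inf
    for (target in c(0.3, 0.5, 0.7, 0.9, 0.99)) {
      t <- threshold_at_precision(curve, target)
      if (is.na(t)) break  # once unattainable, stays unattainable
      expect_gte(t, prev)
      prev <- t
    }
  }
})

test_that("reported operating points are exactly recomputable from raw scores", {
  set.seed(84)
  for (i in 1:20) {
    cs <- random_case(50)
    curve <- pr_curve(cs$scores, cs$labels)
    for (row in c(1L, nrow(curve$points), sample(nrow(curve$points), 1))) {
      t <- curve$points$threshold[row]
      call <- cs$scores >= t
      expect_equal(curve$points$tp[row], sum(call & cs$labels))
      expect_equal(curve$points$recall[row],
                   sum(call & cs$labels) / sum(cs$labels))
      expect_equal(curve$points$specificity[row],
                   sum(!call & !cs$labels) / sum(!cs$labels))
    }
  }
})

test_that("auROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(85)
  for (i in 1:10) {
    cs <- random_case(60)
    ref <- as.numeric(pROC::auc(pROC::roc(cs$labels, cs$scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(cs$scores, cs$labels), ref, tolerance = 1e-12)
  }
})

test_that("sensitivity-targeted search pairs thresholds with specificity", {
  curve <- pr_curve(c(0.9, 0.7, 0.6, 0.4, 0.2),
                    c(TRUE, TRUE, FALSE, TRUE, FALSE))
  res <- threshold_at_sensitivity(curve, 2 / 3)
  expect_gte(res$sensitivity, 2 / 3)
  # the highest threshold reaching the target
  expect_equal(res$threshold, 0.7)
  # perfect classifier reaches sensitivity 1 with specificity 1
  pc <- pr_curve(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(threshold_at_specificity(pc, 0.9)$sensitivity, 1)
})

test_that("stratified recall reports undefined strata as NA", {
  scores <- c(0.9, 0.8, 0.2, 0.7, 0.3, 0.95, 0.1, 0.5)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  regions <- c("donor", "donor", "donor", "acceptor", "acceptor",
               "exon", "exon", "intron")
  sr <- stratified_recall(scores, labels, regions, 0.61)
  expect_equal(sr$recall[sr$region == "donor"], 1)
  expect_equal(sr$recall[sr$region == "acceptor"], 1)
  expect_equal(sr$recall[sr$region == "exon"], 1)
  expect_true(is.na(sr$recall[sr$region == "intron"]))  # no positives there
  # manual confusion check for one stratum at a harsher threshold
  sr2 <- stratified_recall(scores, labels, regions, 0.85)
  expect_equal(sr2$n_called[sr2$region == "donor"], 1L)
  expect_equal(sr2$recall[sr2$region == "donor"], 0.5)
  # threshold above every score: recall 0 where positives exist
  sr3 <- stratified_recall(scores, labels, regions, 2)
  expect_equal(sr3$recall[sr3$region == "donor"], 0)
})

test_that("concordance compares calls at per-tool thresholds", {
  s <- stats::setNames(c(0.9, 0.2, 0.7, 0.1), paste0("v", 1:4))
  y <- c(TRUE, FALSE, FALSE, TRUE)
  same <- concordance(s, s, y, 0.5, 0.5)
  expect_equal(same$concordant_fraction, 1)
  expect_equal(nrow(same$discordant), 0L)
  opp <- concordance(s, 1 - s, y, 0.5, 0.5)
  expect_equal(opp$concordant_fraction, 0)
  expect_equal(nrow(opp$discordant), 4L)
  expect_equal(same$false_positives_a, 1L)  # v3 called but negative
  expect_error(concordance(s, s[1:3], y, 0.5, 0.5), "same variant keys")
  # random fixture against direct computation
  set.seed(86)
  a <- stats::setNames(stats::runif(30), paste0("k", 1:30))
  b <- stats::setNames(stats::runif(30), paste0("k", 1:30))
  yy <- stats::runif(30) < 0.5
  res <- concordance(a, b, yy, 0.6, 0.3)
  expect_equal(res$concordant_fraction, mean((a >= 0.6) == (b >= 0.3)))
  expect_equal(res$false_positives_b, sum(b >= 0.3 & !yy))
})
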