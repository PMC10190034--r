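# The missing-data-tolerant decision tree.

test_that("fractional weighting reproduces the hand-derived toy fixture", {
  # rows: f1 = 1 (neg), NA (neg), 3 (pos), 4 (pos); min_leaf 1, no pruning.
  # Split at 1 <= f1 < 3 -> threshold 2 (gain ratio maximal); the missing
  # row is routed 1/3 left, 2/3 right, giving Laplace leaf probabilities
  # left (0+1)/(4/3+2) = 0.3 and right (2+1)/(8/3+2) = 9/14.
  d <- data.frame(f1 = c(1, NA, 3, 4),
                  label = c("negative", "negative", "positive", "positive"))
  m <- train_tree(d, params = tree_params(min_leaf = 1, prune_confidence = NA))
  p <- predict_score(m, data.frame(f1 = c(1.5, 3, NA)))
  expect_equal(p[1], 0.3, tolerance = 1e-12)
  expect_equal(p[2], 9 / 14, tolerance = 1e-12)
  # all-missing probe: mixture over branch masses 1/3, 2/3
  expect_equal(p[3], (1 / 3) * 0.3 + (2 / 3) * (9 / 14), tolerance = 1e-12)
})

test_that("training and prediction match the oracle on exhaustively enumerated toys", {
  # every labelling of 4 and 5 rows with one missing cell in each position
  probes <- data.frame(f1 = c(0.5, 1.5, 2.5, 3.5, 4.5, NA))
  params <- tree_params(min_leaf = 1, prune_confidence = NA)
  for (n in 4:5) {
    f1_base <- as.numeric(seq_len(n))
    for (lab_bits in 1:(2^n - 2)) {
      y <- as.logical(bitwAnd(lab_bits, 2^(seq_len(n) - 1)) > 0)
      for (miss_at in seq_len(n)) {
        f1 <- f1_base
        f1[miss_at] <- NA
        if (all(is.na(f1[y])) || all(is.na(f1[!y]))) next
        d <- data.frame(f1 = f1,
                        label = ifelse(y, "positive", "negative"))
        m <- train_tree(d, params = params)
        ours <- predict_score(m, probes)
        node <- oracle_train(list(f1 = f1), y)
        ref <- vapply(probes$f1, function(v)
          oracle_predict(node, list(v)), numeric(1))
        expect_equal(ours, ref, tolerance = 1e-12,
                     info = paste("n", n, "labels", lab_bits, "miss", miss_at))
      }
    }
  }
})

test_that("two-feature toys with a missing cell also match the oracle", {
  probes <- expand.grid(f1 = c(0.5, 1.5, 2.5, NA), f2 = c(5, 15, NA))
  params <- tree_params(min_leaf = 1, prune_confidence = NA)
  f1 <- c(1, 2, 3, 1)
  f2 <- c(10, 20, 10, 20)
  for (lab_bits in 1:14) {
    y <- as.logical(bitwAnd(lab_bits, 2^(0:3)) > 0)
    for (miss in list(c(1, 1), c(2, 3), c(1, 4), c(2, 2))) {
      X <- list(f1 = f1, f2 = f2)
      X[[miss[1]]][miss[2]] <- NA
      d <- data.frame(f1 = X$f1, f2 = X$f2,
                      label = ifelse(y, "positive", "negative"))
      m <- train_tree(d, params = params)
      ours <- predict_score(m, probes)
      node <- oracle_train(X, y)
      ref <- vapply(seq_len(nrow(probes)), function(i)
        oracle_predict(node, list(probes$f1[i], probes$f2[i])), numeric(1))
      expect_equal(ours, ref, tolerance = 1e-12,
                   info = paste("labels", lab_bits, "miss", paste(miss, collapse = ",")))
    }
  }
})

test_that("with no missing values prediction equals single-path traversal", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 60
    d <- data.frame(f1 = stats::runif(n), f2 = stats::runif(n),
                    f3 = sample(c("a", "b", "c"), n, replace = TRUE))
    d$label <- ifelse(stats::runif(n) <
                        ifelse(d$f1 > 0.5, 0.85, 0.15), "positive", "negative")
    if (length(unique(d$label)) < 2) next
    m <- train_tree(d)
    ours <- predict_score(m, d)
    ref <- vapply(seq_len(n), function(i)
      single_path_predict(m, as.list(d[i, ])), numeric(1))
    expect_equal(ours, ref, tolerance = 1e-12)
    expect_true(all(ours >= 0 & ours <= 1))
  }
})

test_that("degenerate inputs behave as specified", {
  # a perfectly separating feature yields perfect training accuracy
  d <- data.frame(f1 = c(1, 2, 3, 10, 11, 12),
                  label = rep(c("negative", "positive"), each = 3))
  m <- train_tree(d, params = tree_params(min_leaf = 1))
  p <- predict_score(m, d)
  expect_true(all((p > 0.5) == (d$label == "positive")))
  # a pure positive leaf of n = 8 carries the Laplace probability 0.9
  d8 <- data.frame(f1 = c(rep(1, 4), rep(10, 8)),
                   label = rep(c("negative", "positive"), c(4, 8)))
  m8 <- train_tree(d8, params = tree_params(prune_confidence = NA))
  expect_equal(max(predict_score(m8, data.frame(f1 = c(10)))),
               (8 + 1) / (8 + 2), tolerance = 1e-12)
  # labels independent of features: single leaf at the smoothed prior
  dind <- data.frame(f1 = rep(c(1, 2), 10),
                     label = rep(c("positive", "negative"), each = 10))
  mind <- train_tree(dind)
  expect_equal(mind$root$type, "leaf")
  expect_equal(predict_score(mind, data.frame(f1 = 1)),
               (10 + 1) / (20 + 2))
  # single-class input and empty registry are errors
  expect_error(train_tree(data.frame(f1 = 1:3, label = rep("positive", 3))),
               "both classes")
  expect_error(train_tree(d, features = character(0)), "empty feature")
  # unknown feature at prediction time is an error
  expect_error(predict_score(m, data.frame(zzz = 1)), "absent")
})

test_that("training is invariant to row order and feature renaming", {
  d <- toy_training(50, seed = 72)
  d$f1[c(3, 17)] <- NA
  m1 <- train_tree(d)
  set.seed(73)
  perm <- sample(nrow(d))
  m2 <- train_tree(d[perm, ])
  probe <- data.frame(f1 = c(0.1, 0.9, NA), f2 = c(0, 0, NA))
  expect_equal(predict_score(m1, probe), predict_score(m2, probe),
               tolerance = 1e-12)
  # bijective renaming (same registry order)
  d3 <- d
  names(d3)[1:2] <- c("alpha", "beta")
  m3 <- train_tree(d3)
  probe3 <- probe
  names(probe3) <- c("alpha", "beta")
  expect_equal(predict_score(m1, probe), predict_score(m3, probe3),
               tolerance = 1e-12)
})

test_that("feature importance reflects routed training mass", {
  d <- data.frame(f1 = c(1, 2, 3, 10, 11, 12),
                  f2 = c(1, 9, 1, 9, 1, 9),
                  label = rep(c("negative", "positive"), each = 3))
  m <- train_tree(d, params = tree_params(min_leaf = 1))
  imp <- feature_importance(m)
  expect_equal(unname(imp["f1"]), 100)
  expect_equal(unname(imp["f2"]), 0)
  # nested two-feature tree: hand-computed mass fractions
  d2 <- data.frame(f1 = c(1, 1, 1, 1, 10, 10, 10, 10),
                   f2 = c(1, 1, 9, 9, 1, 1, 1, 1),
                   label = c("negative", "negative", "positive", "positive",
                             "positive", "positive", "positive", "positive"))
  m2 <- train_tree(d2, params = tree_params(min_leaf = 1, prune_confidence = NA))
  imp2 <- feature_importance(m2)
  # root splits on f1 (mass 8), child on f2 (mass 4): importances 100 and 50
  expect_equal(unname(imp2[order(-imp2)][1:2]), c(100, 50))
})

test_that("cross-validation is stratified, deterministic and audit-friendly", {
  d <- toy_training(40, seed = 74)
  cv1 <- cross_validate(d, k = 4, seed = 9)
  cv2 <- cross_validate(d, k = 4, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(sort(unique(cv1$folds)), 1:4)
  # every fold holds both classes
  for (f in 1:4) {
    expect_true(length(unique(d$label[cv1$folds == f])) == 2L)
  }
  expect_error(cross_validate(d, k = 25), "too few")
  expect_error(cross_validate(d, k = 1), "k must be")
  # clean separation on f1 gives near-perfect CV metrics
  expect_gt(cv1$mean_auroc, 0.95)
})

test_that("model save/load round-trips predictions bit-exactly", {
  d <- toy_training(60, seed = 75)
  d$f3 <- sample(c("x", "y"), 60, replace = TRUE)
  d$f1[c(2, 30)] <- NA
  m <- train_tree(d)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  probe <- data.frame(f1 = c(0.2, NA, 0.8), f2 = c(1, -1, NA),
                      f3 = c("x", "z", NA))
  expect_identical(predict_score(m, probe), predict_score(m2, probe))
  expect_error(load_model(tempfile()), "not found")
  # tampering with the registry is caught by the hash
  p <- jsonlite::read_json(path)
  p$registry[[1]] <- "tampered"
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "hash mismatch")
})

test_that("a tree recovers held-out performance close to the Bayes score", {
  set.seed(76)
  gen <- function(n) {
    x1 <- stats::runif(n); x2 <- stats::runif(n)
    bayes <- ifelse(x1 > 0.5, ifelse(x2 > 0.5, 0.95, 0.7), 0.1)
    data.frame(f1 = x1, f2 = x2, bayes = bayes,
               label = ifelse(stats::runif(n) < bayes, "positive", "negative"))
  }
  train <- gen(1500); test <- gen(1000)
  m <- train_tree(train[, c("f1", "f2", "label")])
  sc <- predict_score(m, test)
  auc_tree <- roc_auc(sc, test$label)
  auc_bayes <- roc_auc(test$bayes, test$label)
  expect_gt(auc_tree, auc_bayes - 0.02)
})
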