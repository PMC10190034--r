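# Missing-data-tolerant decision tree (C4.5/C5.0 family).
#
# The learner is authored here rather than wrapped from another package so
# that the missing-value semantics the consensus model depends on are
# explicit and testable:
#   * splits are chosen by information gain ratio computed on the rows where
#     the candidate feature is observed, with the gain scaled by the
#     observed weight fraction;
#   * rows missing the chosen split feature are sent down every branch with
#     their weight multiplied by the observed branch mass fraction
#     (fractional instance weighting) -- no imputation, ever;
#   * leaves carry Laplace-smoothed positive-class probabilities
#     (pos + 1) / (n + 2), so the tree emits a continuous 0-1 score;
#   * pruning is pessimistic (error-based, binomial upper confidence bound).
# Everything is deterministic given (data, params): ties in gain ratio break
# toward the lowest feature-registry index, then the lowest threshold;
# numeric candidate thresholds are midpoints of sorted observed values.

#' Decision-tree training parameters
#'
#' @param min_leaf minimum observed weight per branch for a split to be
#'   admissible (default 2).
#' @param prune_confidence confidence level of the pessimistic-error
#'   pruning bound (default 0.25); `NA` disables pruning.
#' @param seed integer recorded in the model metadata (training itself is
#'   deterministic).
#' @param max_depth recursion guard (default 30).
#' @return object of class `tree_params`.
#' @export
tree_params <- function(min_leaf = 2, prune_confidence = 0.25, seed = 1L,
                        max_depth = 30L) {
  structure(list(min_leaf = min_leaf, prune_confidence = prune_confidence,
                 seed = as.integer(seed), max_depth = as.integer(max_depth)),
            class = "tree_params")
}

entropy2 <- function(wpos, wneg) {
  W <- wpos + wneg
  if (W <= 0) return(0)
  p <- c(wpos, wneg) / W
  p <- p[p > 0]
  -sum(p * log2(p))
}

make_leaf <- function(wpos, wneg) {
  list(type = "leaf", wpos = wpos, wneg = wneg,
       prob = (wpos + 1) / (wpos + wneg + 2))
}

# Best admissible binary threshold split on a numeric feature.
best_numeric_split <- function(xv, yv, wv, W_tot, W_miss, min_leaf) {
  ord <- order(xv)
  v <- xv[ord]; yi <- yv[ord]; wi <- wv[ord]
  W_obs <- sum(wi)
  wp_obs <- sum(wi[yi])
  H_obs <- entropy2(wp_obs, W_obs - wp_obs)
  if (H_obs <= 0) return(NULL)
  cw <- cumsum(wi); cwp <- cumsum(wi * yi)
  n <- length(v)
  cand <- which(v[-n] < v[-1L])            # boundaries between distinct values
  if (!length(cand)) return(NULL)
  Wl <- cw[cand]; Wpl <- cwp[cand]
  Wr <- W_obs - Wl; Wpr <- wp_obs - Wpl
  ok <- Wl >= min_leaf & Wr >= min_leaf
  if (!any(ok)) return(NULL)
  Hl <- vapply(which(ok), function(i) entropy2(Wpl[i], Wl[i] - Wpl[i]), numeric(1))
  Hr <- vapply(which(ok), function(i) entropy2(Wpr[i], Wr[i] - Wpr[i]), numeric(1))
  info <- (Wl[ok] * Hl + Wr[ok] * Hr) / W_obs
  gain <- (W_obs / W_tot) * (H_obs - info)
  fr <- cbind(Wl[ok], Wr[ok], if (W_miss > 0) W_miss else NULL) / W_tot
  si <- apply(fr, 1L, function(f) { f <- f[f > 0]; -sum(f * log2(f)) })
  gr <- ifelse(si > 0, gain / si, -Inf)
  best <- which(gr > max(gr) - 1e-12)[1L]   # lowest threshold among ties
  idx <- which(ok)[best]
  list(kind = "numeric",
       threshold = (v[cand[idx]] + v[cand[idx] + 1L]) / 2,
       gain = gain[best], gain_ratio = gr[best],
       branch_of = function(x) ifelse(x <= (v[cand[idx]] + v[cand[idx] + 1L]) / 2, 1L, 2L),
       n_branches = 2L)
}

# Multiway split on a categorical feature (one branch per observed level).
best_categorical_split <- function(xv, yv, wv, W_tot, W_miss, min_leaf) {
  lev <- sort(unique(xv))
  if (length(lev) < 2L) return(NULL)
  W_obs <- sum(wv)
  wp_obs <- sum(wv[yv])
  H_obs <- entropy2(wp_obs, W_obs - wp_obs)
  if (H_obs <= 0) return(NULL)
  Wb <- vapply(lev, function(l) sum(wv[xv == l]), numeric(1))
  Wpb <- vapply(lev, function(l) sum(wv[xv == l & yv]), numeric(1))
  if (sum(Wb >= min_leaf) < 2L) return(NULL)
  Hb <- mapply(function(wp, w) entropy2(wp, w - wp), Wpb, Wb)
  info <- sum(Wb * Hb) / W_obs
  gain <- (W_obs / W_tot) * (H_obs - info)
  fr <- c(Wb, if (W_miss > 0) W_miss) / W_tot
  fr <- fr[fr > 0]
  si <- -sum(fr * log2(fr))
  if (si <= 0) return(NULL)
  list(kind = "categorical", levels = lev, gain = gain, gain_ratio = gain / si,
       branch_of = function(x) match(x, lev), n_branches = length(lev))
}

#' Train the consensus decision tree
#'
#' @param data data.frame of features plus a label column; features may be
#'   numeric, logical (treated as 0/1 numeric) or character/factor
#'   (categorical, multiway splits). `NA` marks a missing value.
#' @param label name of the label column; values `positive`/`negative`
#'   (factors and logicals accepted).
#' @param params a [tree_params()].
#' @param features feature registry (ordered character vector); defaults to
#'   every non-label column. The order fixes tie-breaking and is stored in
#'   the model.
#' @return object of class `splice_tree`.
#' @export
train_tree <- function(data, label = "label", params = tree_params(),
                       features = NULL) {
  if (is.null(features)) features <- setdiff(names(data), label)
  if (!length(features)) stop("empty feature registry")
  miss <- setdiff(c(features, label), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- label_to_logical(data[[label]])
  if (anyNA(y)) stop("labels must not be missing")
  if (!any(y) || all(y)) stop("training data must contain both classes")

  kinds <- vapply(features, function(f) {
    col <- data[[f]]
    if (is.numeric(col) || is.logical(col) || is.integer(col)) "numeric"
    else "categorical"
  }, character(1))
  X <- lapply(features, function(f) {
    col <- data[[f]]
    if (is.logical(col)) as.numeric(col)
    else if (is.factor(col)) as.character(col)
    else col
  })
  names(X) <- features
  n <- length(y)

  build <- function(rows, w, depth) {
    wpos <- sum(w[y[rows]]); W <- sum(w); wneg <- W - wpos
    leaf <- make_leaf(wpos, wneg)
    leaf$W <- W
    if (entropy2(wpos, wneg) <= 0 || depth >= params$max_depth ||
        W < 2 * params$min_leaf)
      return(leaf)
    best <- NULL
    for (j in seq_along(features)) {
      xv_all <- X[[j]][rows]
      obs <- !is.na(xv_all)
      if (!any(obs)) next
      W_miss <- sum(w[!obs])
      sp <- if (kinds[j] == "numeric") {
        best_numeric_split(xv_all[obs], y[rows][obs], w[obs], W, W_miss,
                           params$min_leaf)
      } else {
        best_categorical_split(xv_all[obs], y[rows][obs], w[obs], W, W_miss,
                               params$min_leaf)
      }
      if (is.null(sp) || sp$gain <= 1e-12) next
      if (is.null(best) || sp$gain_ratio > best$gain_ratio + 1e-12) {
        sp$feature <- features[j]
        best <- sp
      }
    }
    if (is.null(best)) return(leaf)

    xv_all <- X[[best$feature]][rows]
    obs <- !is.na(xv_all)
    br_obs <- rep(NA_integer_, length(rows))
    br_obs[obs] <- best$branch_of(xv_all[obs])
    Wb <- vapply(seq_len(best$n_branches),
                 function(b) sum(w[which(br_obs == b)]), numeric(1))
    mass <- Wb / sum(Wb)
    children <- vector("list", best$n_branches)
    for (b in seq_len(best$n_branches)) {
      in_b <- which(br_obs == b)
      miss_rows <- which(!obs)
      child_rows <- c(rows[in_b], rows[miss_rows])
      child_w <- c(w[in_b], w[miss_rows] * mass[b])
      keep <- child_w > 1e-12
      children[[b]] <- build(child_rows[keep], child_w[keep], depth + 1L)
    }
    node <- list(type = "split", feature = best$feature, kind = best$kind,
                 children = children, mass = mass,
                 wpos = wpos, wneg = wneg, W = W)
    if (best$kind == "numeric") node$threshold <- best$threshold
    else node$levels <- best$levels
    node
  }

  root <- build(seq_len(n), rep(1, n), 0L)
  if (!is.na(params$prune_confidence))
    root <- prune_node(root, params$prune_confidence)$node

  structure(list(root = root, registry = features,
                 kinds = stats::setNames(kinds, features),
                 registry_hash = st_hash(c(features, kinds)),
                 params = unclass(params),
                 n_train = n, n_pos = sum(y), version = 1L),
            class = "splice_tree")
}

label_to_logical <- function(lab) {
  if (is.logical(lab)) return(lab)
  if (is.factor(lab)) lab <- as.character(lab)
  if (is.numeric(lab)) return(lab != 0)
  lv <- unique(lab[!is.na(lab)])
  if (!all(lv %in% c("positive", "negative")))
    stop("labels must be 'positive'/'negative' (got: ",
         paste(utils::head(setdiff(lv, c("positive", "negative"))), collapse = ", "), ")")
  lab == "positive"
}

# Pessimistic upper bound on the error rate (binomial upper confidence
# limit at level 1 - cf), evaluated on possibly fractional counts.
pessimistic_ucb <- function(E, N, cf) {
  if (N <= 0) return(0)
  stats::qbeta(1 - cf, E + 1, max(N - E, 1e-9))
}

prune_node <- function(node, cf) {
  W <- node$W
  E <- W - max(node$wpos, node$wneg)
  leaf_err <- W * pessimistic_ucb(E, W, cf)
  if (node$type == "leaf") {
    node$pred_err <- leaf_err
    return(list(node = node, err = leaf_err))
  }
  sub_err <- 0
  for (b in seq_along(node$children)) {
    pr <- prune_node(node$children[[b]], cf)
    node$children[[b]] <- pr$node
    sub_err <- sub_err + pr$err
  }
  if (leaf_err <= sub_err + 1e-9) {
    lf <- make_leaf(node$wpos, node$wneg)
    lf$W <- W
    lf$pred_err <- leaf_err
    return(list(node = lf, err = leaf_err))
  }
  list(node = node, err = sub_err)
}

#' Predict splice-impact scores
#'
#' Standard single-path traversal when every split feature is observed;
#' when a split feature is missing (or a categorical value was unseen in
#' training), the prediction is the average of the branch predictions
#' weighted by the stored training branch mass fractions.
#'
#' @param tree a `splice_tree`.
#' @param newdata data.frame containing every feature in the tree's
#'   registry (unknown registry features are an error).
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_score <- function(tree, newdata) {
  miss <- setdiff(tree$registry, names(newdata))
  if (length(miss))
    stop("feature(s) absent from newdata: ", paste(miss, collapse = ", "))
  rec <- function(node, fv) {
    if (node$type == "leaf") return(node$prob)
    val <- fv[[node$feature]]
    if (is.logical(val)) val <- as.numeric(val)
    if (is.factor(val)) val <- as.character(val)
    if (is.na(val) ||
        (node$kind == "categorical" && !val %in% node$levels)) {
      return(sum(node$mass * vapply(node$children, rec, numeric(1), fv = fv)))
    }
    b <- if (node$kind == "numeric") {
      if (val <= node$threshold) 1L else 2L
    } else match(val, node$levels)
    rec(node$children[[b]], fv)
  }
  vapply(seq_len(nrow(newdata)), function(i)
    rec(tree$root, as.list(newdata[i, tree$registry, drop = FALSE])),
    numeric(1))
}

#' Usage-based feature importance
#'
#' Importance of a feature is the total training mass routed through the
#' internal nodes that split on it, as a fraction of the root mass,
#' normalised so the largest importance is 100. Features never used by a
#' split score 0.
#'
#' @param tree a `splice_tree`.
#' @return named numeric vector over the tree's feature registry.
#' @export
feature_importance <- function(tree) {
  acc <- stats::setNames(rep(0, length(tree$registry)), tree$registry)
  walk <- function(node) {
    if (node$type == "leaf") return(invisible())
    acc[node$feature] <<- acc[node$feature] + node$W
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  acc <- acc / tree$root$W
  if (max(acc) > 0) acc <- 100 * acc / max(acc)
  acc
}

#' Stratified k-fold cross-validation
#'
#' Deterministic given `seed`; folds are stratified by class and returned
#' for audit. Errors if either class has fewer members than `k`.
#'
#' @param data labelled feature data.frame (see [train_tree()]).
#' @param k number of folds (default 10).
#' @param params a [tree_params()].
#' @param seed fold-assignment seed.
#' @param label label column name.
#' @param features feature registry passed through to [train_tree()].
#' @return list with `folds` (fold id per row), `metrics` (per-fold data
#'   frame with auROC/auPRC) and `mean_auroc`, `mean_auprc`.
#' @export
cross_validate <- function(data, k = 10L, params = tree_params(), seed = 1L,
                           label = "label", features = NULL) {
  y <- label_to_logical(data[[label]])
  if (k < 2L) stop("k must be >= 2")
  if (min(sum(y), sum(!y)) < k)
    stop("too few members of a class for ", k, "-fold stratification")
  set.seed(seed)
  folds <- integer(length(y))
  folds[y] <- sample(rep_len(seq_len(k), sum(y)))
  folds[!y] <- sample(rep_len(seq_len(k), sum(!y)))
  metrics <- data.frame(fold = seq_len(k), auroc = NA_real_, auprc = NA_real_)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- train_tree(data[!test, , drop = FALSE], label = label,
                      params = params, features = features)
    sc <- predict_score(fit, data[test, , drop = FALSE])
    metrics$auroc[f] <- roc_auc(sc, y[test])
    metrics$auprc[f] <- pr_curve(sc, y[test])$auprc
  }
  list(folds = folds, metrics = metrics,
       mean_auroc = mean(metrics$auroc), mean_auprc = mean(metrics$auprc))
}

#' Save / load a trained tree
#'
#' The model is serialised as versioned JSON at full numeric precision, so
#' a round trip preserves predictions bit-exactly. Loading verifies the
#' stored feature-registry hash.
#'
#' @param tree a `splice_tree`.
#' @param path output (input) file path.
#' @return `load_model` returns the `splice_tree`; `save_model` the path,
#'   invisibly.
#' @export
save_model <- function(tree, path) {
  payload <- list(format = "splicetree-model", version = tree$version,
                  registry = tree$registry, kinds = as.list(tree$kinds),
                  registry_hash = tree$registry_hash, params = tree$params,
                  n_train = tree$n_train, n_pos = tree$n_pos,
                  root = tree$root)
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- jsonlite::read_json(path)
  if (!identical(p$format, "splicetree-model"))
    stop("not a splicetree model file: ", path)
  registry <- unlist(p$registry)
  kinds <- stats::setNames(unlist(p$kinds), names(p$kinds))
  kinds <- kinds[registry]
  if (!identical(st_hash(c(registry, unname(kinds))), p$registry_hash))
    stop("feature registry hash mismatch in ", path)
  rebuild <- function(nd) {
    if (identical(nd$type, "leaf")) {
      out <- list(type = "leaf", wpos = nd$wpos, wneg = nd$wneg,
                  prob = nd$prob, W = nd$W)
      return(out)
    }
    node <- list(type = "split", feature = nd$feature, kind = nd$kind,
                 children = lapply(nd$children, rebuild),
                 mass = as.numeric(unlist(nd$mass)),
                 wpos = nd$wpos, wneg = nd$wneg, W = nd$W)
    if (nd$kind == "numeric") node$threshold <- nd$threshold
    else node$levels <- as.character(unlist(nd$levels))
    node
  }
  structure(list(root = rebuild(p$root), registry = registry, kinds = kinds,
                 registry_hash = p$registry_hash, params = p$params,
                 n_train = p$n_train, n_pos = p$n_pos, version = p$version),
            class = "splice_tree")
}
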