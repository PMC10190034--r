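# Independent oracle implementations used to cross-check the package's
# algorithms. These are deliberately naive (plain loops, no shared code
# with the package internals).

# --- PWM oracle -------------------------------------------------------

# Score of every window of `seq` under matrix `mat` (width x 4, ACGT),
# plain nested loops.
oracle_window_scores <- function(seq, mat) {
  w <- nrow(mat)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < w) return(numeric(0))
  sapply(seq_len(n - w + 1L), function(i) {
    s <- 0
    for (k in seq_len(w)) {
      j <- match(ch[i + k - 1L], c("A", "C", "G", "T"))
      if (!is.na(j)) s <- s + mat[k, j]
    }
    s
  })
}

# Brute-force delta: construct the full alternate haplotype, score every
# window of each haplotype that overlaps the changed bases, and subtract.
oracle_pwm_delta <- function(chromseq, start, ref_core, alt_core, mat,
                             strand = "+") {
  w <- nrow(mat)
  len <- nchar(chromseq)
  alt_hap <- paste0(substr(chromseq, 1L, start - 1L), alt_core,
                    substr(chromseq, start + nchar(ref_core), len))
  win_max <- function(hap, core_len) {
    lo <- max(1L, start - w + 1L)
    hi <- if (core_len > 0L) start + core_len - 1L else start - 1L
    hi <- min(hi, nchar(hap) - w + 1L)
    if (hi < lo) return(NA_real_)
    best <- -Inf
    for (i in lo:hi) {
      win <- substr(hap, i, i + w - 1L)
      if (strand == "-")
        win <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      sc <- oracle_window_scores(win, mat)
      if (length(sc) && sc > best) best <- sc
    }
    best
  }
  unname(win_max(alt_hap, nchar(alt_core)) - win_max(chromseq, nchar(ref_core)))
}

# --- fractional-weighting tree oracle ---------------------------------

# Naive C4.5-style trainer over numeric features: gain ratio on observed
# rows scaled by the observed fraction, split info over branch + missing
# mass, midpoint thresholds, fractional routing of missing rows. Ties
# break to the earliest feature column, then the lowest threshold. No
# pruning.
oracle_entropy <- function(wp, wn) {
  W <- wp + wn
  if (W <= 0) return(0)
  h <- 0
  for (p in c(wp, wn) / W) if (p > 0) h <- h - p * log2(p)
  h
}

oracle_train <- function(X, y, w = rep(1, length(y)), min_leaf = 1) {
  W <- sum(w)
  wp <- sum(w[y])
  if (oracle_entropy(wp, W - wp) <= 0 || W < 2 * min_leaf)
    return(list(leaf = TRUE, prob = (wp + 1) / (W + 2)))
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    obs <- !is.na(x)
    if (sum(obs) == 0) next
    W_obs <- sum(w[obs]); W_miss <- W - W_obs
    wp_obs <- sum(w[obs & y])
    H_obs <- oracle_entropy(wp_obs, W_obs - wp_obs)
    vals <- sort(unique(x[obs]))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1L]) / 2) {
      l <- obs & x <= t; r <- obs & x > t
      Wl <- sum(w[l]); Wr <- sum(w[r])
      if (Wl < min_leaf || Wr < min_leaf) next
      info <- (Wl * oracle_entropy(sum(w[l & y]), Wl - sum(w[l & y])) +
               Wr * oracle_entropy(sum(w[r & y]), Wr - sum(w[r & y]))) / W_obs
      gain <- (W_obs / W) * (H_obs - info)
      fr <- c(Wl, Wr, W_miss) / W
      fr <- fr[fr > 0]
      si <- -sum(fr * log2(fr))
      if (si <= 0) next
      gr <- gain / si
      if (gain > 1e-12 && (is.null(best) || gr > best$gr + 1e-12)) {
        best <- list(gr = gr, j = j, t = t)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = (wp + 1) / (W + 2)))
  x <- X[[best$j]]
  obs <- !is.na(x)
  l <- obs & x <= best$t; r <- obs & x > best$t
  Wl <- sum(w[l]); Wr <- sum(w[r])
  mass <- c(Wl, Wr) / (Wl + Wr)
  sub <- function(keep, share) {
    rows <- keep | !obs
    wn <- ifelse(keep, w, w * share)[rows]
    Xn <- lapply(X, function(col) col[rows])
    oracle_train(Xn, y[rows], wn, min_leaf)
  }
  list(leaf = FALSE, j = best$j, t = best$t, mass = mass,
       left = sub(l, mass[1L]), right = sub(r, mass[2L]))
}

oracle_predict <- function(node, fv) {
  if (node$leaf) return(node$prob)
  v <- fv[[node$j]]
  if (is.na(v)) {
    return(node$mass[1L] * oracle_predict(node$left, fv) +
           node$mass[2L] * oracle_predict(node$right, fv))
  }
  if (v <= node$t) oracle_predict(node$left, fv)
  else oracle_predict(node$right, fv)
}

# Single-path traversal of a trained splice_tree (valid only when every
# split feature is observed): the no-missing reference behaviour.
single_path_predict <- function(tree, row) {
  node <- tree$root
  while (node$type != "leaf") {
    val <- row[[node$feature]]
    if (is.logical(val)) val <- as.numeric(val)
    stopifnot(!is.na(val))
    b <- if (node$kind == "numeric") {
      if (val <= node$threshold) 1L else 2L
    } else match(as.character(val), node$levels)
    node <- node$children[[b]]
  }
  node$prob
}

# --- PR machinery oracle ----------------------------------------------

# Enumerate every distinct threshold and compute the confusion matrix
# directly.
oracle_pr <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    call <- scores >= t
    tp <- sum(call & y); fp <- sum(call & !y)
    fn <- sum(!call & y); tn <- sum(!call & !y)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = tp / (tp + fp), recall = tp / sum(y),
               specificity = tn / sum(!y))
  })
  pts <- do.call(rbind, rows)
  au <- 0; prev_r <- 0
  for (i in seq_len(nrow(pts))) {
    au <- au + (pts$recall[i] - prev_r) * pts$precision[i]
    prev_r <- pts$recall[i]
  }
  f1 <- ifelse(pts$precision + pts$recall > 0,
               2 * pts$precision * pts$recall / (pts$precision + pts$recall), 0)
  best_f1 <- which(f1 == max(f1))[1L]   # points ordered by decreasing thr
  ok_p95 <- pts$threshold[pts$precision >= 0.95]
  list(points = pts, auprc = au,
       f1_threshold = pts$threshold[best_f1],
       f1_sensitivity = pts$recall[best_f1],
       f1_specificity = pts$specificity[best_f1],
       thr_at_p95 = if (length(ok_p95)) min(ok_p95) else NA_real_,
       thr_at_spec = function(target) {
         ok <- pts$threshold[pts$specificity >= target]
         if (length(ok)) min(ok) else max(pts$threshold)
       })
}

# Apply a variant (core representation) to a sequence: the haplotype
# oracle used for normalisation and decomposition checks.
apply_to_seq <- function(chromseq, start, ref_core, alt_core) {
  stopifnot(substr(chromseq, start, start + nchar(ref_core) - 1L) == ref_core ||
              nchar(ref_core) == 0L)
  paste0(substr(chromseq, 1L, start - 1L), alt_core,
         substr(chromseq, start + nchar(ref_core), nchar(chromseq)))
}
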