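# Independent oracles kept deliberately naive: they re-derive the quantity
# from its definition, not from the implementation under test.

# Projection-deflation (NIPALS-style) PLS1. Tracks the accumulated column
# transform G so each component's direction can be mapped back to the
# original coordinates, unit-normalized, and its cov^2 with y compared to
# the SIMPLS fit.
oracle_pls_cov2 <- function(x, y, m) {
  p <- ncol(x)
  G <- diag(p)
  xc <- x
  covs <- numeric(0)
  for (i in seq_len(m)) {
    w <- crossprod(xc, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- xc %*% w
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    v_orig <- G %*% w
    v_orig <- v_orig / sqrt(sum(v_orig^2))
    covs <- c(covs, stats::cov(x %*% v_orig, y)^2)
    G <- G %*% (diag(p) - w %*% (crossprod(t_, xc) / tt))
    xc <- xc - t_ %*% (crossprod(t_, xc) / tt)
  }
  covs
}

# AUROC as the exhaustive concordant positive-negative pair fraction,
# ties counting 1/2.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# AUPR by brute-force step summation: tied blocks are subdivided into many
# fractional steps with linearly interpolated TP/FP counts, and
# precision * d(recall) accumulated.
oracle_aupr_steps <- function(scores, labels, steps = 20000L) {
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  n_pos <- sum(l)
  blocks <- split(l, cumsum(!duplicated(s)))
  tp <- 0; fp <- 0; aupr <- 0
  for (b in blocks) {
    dp <- sum(b)
    dn <- length(b) - dp
    if (dp > 0) {
      ts <- (seq_len(steps) - 0.5) / steps
      prec <- (tp + ts * dp) / (tp + ts * dp + fp + ts * dn)
      aupr <- aupr + (dp / n_pos) * mean(prec)
    }
    tp <- tp + dp
    fp <- fp + dn
  }
  aupr
}

# Random evaluation instance over a small gene universe.
random_eval_instance <- function(n_pairs, n_pos, n_distinct_scores = NULL) {
  genes <- paste0("G", seq_len(ceiling(sqrt(n_pairs)) + 2))
  u <- expand.grid(regulator = genes, target = genes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- u[u$regulator != u$target, , drop = FALSE][seq_len(n_pairs), ]
  pos <- u[sample.int(n_pairs, n_pos), , drop = FALSE]
  scores <- if (is.null(n_distinct_scores) || is.na(n_distinct_scores))
    stats::runif(n_pairs) else
    sample(seq_len(n_distinct_scores), n_pairs, replace = TRUE) / n_distinct_scores
  pred <- data.frame(u, score = scores)
  pred <- pred[order(-pred$score, pred$regulator, pred$target), ]
  labels <- as.integer(paste(u$regulator, u$target) %in%
                         paste(pos$regulator, pos$target))
  list(universe = u, positives = pos, predictions = pred,
       scores = scores, labels = labels,
       gold = gold_standard(pos, universe = u))
}

# Small centered random regression instance.
random_centered_instance <- function(n, p) {
  center_xy(matrix(stats::rnorm(n * p), n, p), stats::rnorm(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
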