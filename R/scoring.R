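.pair_key <- function(reg, tgt) paste(reg, tgt, sep = "\r")

#' Construct a gold standard of known regulatory edges
#'
#' @param positives `data.frame` (or 2-column matrix) of known
#'   regulator-to-target edges, columns `regulator`, `target`.
#' @param universe Optional `data.frame` of all scorable (eligible)
#'   regulator-target pairs; pairs outside it are never evaluated. When
#'   omitted it defaults, at evaluation time, to all non-self pairs from the
#'   positives' regulator set to every gene mentioned.
#' @return Object of class `"gold_standard"`.
#' @export
gold_standard <- function(positives, universe = NULL) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  if (ncol(positives) < 2L) stop("positives need regulator and target columns")
  names(positives)[1:2] <- c("regulator", "target")
  positives <- positives[, 1:2]
  if (any(positives$regulator == positives$target)) {
    stop("gold standard contains self-edges")
  }
  if (anyDuplicated(.pair_key(positives$regulator, positives$target))) {
    stop("gold standard contains duplicate edges")
  }
  if (!is.null(universe)) {
    universe <- as.data.frame(universe, stringsAsFactors = FALSE)
    names(universe)[1:2] <- c("regulator", "target")
    universe <- universe[, 1:2]
    if (!all(.pair_key(positives$regulator, positives$target) %in%
             .pair_key(universe$regulator, universe$target))) {
      stop("all positive edges must lie in the eligible universe")
    }
  }
  structure(list(positives = positives, universe = universe),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard:", nrow(x$positives), "positive edge(s);",
      if (is.null(x$universe)) "default eligible universe"
      else paste(nrow(x$universe), "eligible pair(s)"), "\n")
  invisible(x)
}

.default_universe <- function(gold) {
  regs <- unique(gold$positives$regulator)
  genes <- unique(c(gold$positives$regulator, gold$positives$target))
  u <- expand.grid(regulator = regs, target = genes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u[u$regulator != u$target, , drop = FALSE]
}

# AUPR of a ranked list given cumulative tie blocks. Within a block of tied
# scores the PR curve is traced by linear interpolation of TP and FP counts
# (so an all-tied ranking integrates to the positive prevalence).
.aupr_blocks <- function(tp_cum, fp_cum, n_pos) {
  tp0 <- c(0, utils::head(tp_cum, -1))
  fp0 <- c(0, utils::head(fp_cum, -1))
  dtp <- tp_cum - tp0
  dfp <- fp_cum - fp0
  contrib <- numeric(length(tp_cum))
  for (b in seq_along(tp_cum)) {
    bb <- dtp[b]
    if (bb == 0) next
    a <- tp0[b]
    cc <- tp0[b] + fp0[b]
    d <- bb + dfp[b]
    # integral_0^1 (a + b t) / (c + d t) dt
    int <- if (cc == 0 && a == 0) {
      bb / d
    } else {
      bb / d + (a * d - bb * cc) / d^2 * log((cc + d) / cc)
    }
    contrib[b] <- (bb / n_pos) * int
  }
  sum(contrib)
}

#' Evaluate ranked edge predictions against a gold standard
#'
#' Scores a ranked prediction list the DREAM way: the area under the ROC
#' curve is computed by the Mann-Whitney rank statistic with midrank tie
#' handling (each tied positive-negative pair contributes 1/2 concordance),
#' and the area under the precision-recall curve by stepping through the
#' ranked list with tied scores processed as a block under linear
#' interpolation of the true/false positive counts. Eligible pairs missing
#' from the prediction list are appended below every listed pair as a
#' single tied block.
#'
#' @param predictions A ranked edge `data.frame` (columns `regulator`,
#'   `target`, `score`), e.g. from [rank_edges()], or a `"plsnet"` fit.
#' @param gold A `"gold_standard"` object (see [gold_standard()],
#'   [read_gold()], [as_gold_standard()]).
#' @return Object of class `"grn_eval"`: list with `aupr`, `auroc`,
#'   `n_positives`, `n_negatives`, and `curves` (`pr` and `roc` point
#'   `data.frame`s for plotting).
#' @examples
#' gs <- gold_standard(data.frame(regulator = "G1", target = c("G2", "G3")))
#' pred <- data.frame(regulator = c("G1", "G1"), target = c("G2", "G3"),
#'                    score = c(2, 1))
#' evaluate_predictions(pred, gs)  # perfect ranking: AUPR = AUROC = 1
#' @export
evaluate_predictions <- function(predictions, gold) {
  if (inherits(predictions, "plsnet")) predictions <- rank_edges(predictions)
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "score") %in% names(predictions))) {
    names(predictions)[1:3] <- c("regulator", "target", "score")
  }
  if (!inherits(gold, "gold_standard")) {
    gold <- gold_standard(gold)
  }
  universe <- if (is.null(gold$universe)) .default_universe(gold) else
    gold$universe
  ukey <- .pair_key(universe$regulator, universe$target)
  pkey <- .pair_key(predictions$regulator, predictions$target)
  if (anyDuplicated(pkey)) stop("duplicate predicted edges")
  keep <- pkey %in% ukey
  predictions <- predictions[keep, , drop = FALSE]
  pkey <- pkey[keep]

  gkey <- .pair_key(gold$positives$regulator, gold$positives$target)
  if (!all(gkey %in% ukey)) {
    stop("gold positives outside the eligible universe")
  }
  labels <- as.integer(ukey %in% gkey)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined metric: need at least one positive and one negative pair")
  }
  scores <- rep(NA_real_, length(ukey))
  scores[match(pkey, ukey)] <- predictions$score
  # unlisted eligible pairs rank below every listed pair, all tied
  if (anyNA(scores)) {
    floor_score <- if (all(is.na(scores))) 0 else min(scores, na.rm = TRUE) - 1
    scores[is.na(scores)] <- floor_score
  }

  # AUROC: midrank Mann-Whitney
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # tie blocks in descending score order
  ord <- order(-scores)
  s_ord <- scores[ord]
  l_ord <- labels[ord]
  block <- cumsum(!duplicated(s_ord))
  tp_cum <- cumsum(l_ord)
  fp_cum <- cumsum(1L - l_ord)
  last <- !duplicated(block, fromLast = TRUE)
  tp_b <- tp_cum[last]
  fp_b <- fp_cum[last]
  aupr <- .aupr_blocks(tp_b, fp_b, n_pos)

  pr <- data.frame(recall = c(0, tp_b / n_pos),
                   precision = c(NA, ifelse(tp_b + fp_b > 0,
                                            tp_b / (tp_b + fp_b), NA)))
  roc <- data.frame(fpr = c(0, fp_b / n_neg), tpr = c(0, tp_b / n_pos))
  structure(list(aupr = aupr, auroc = auroc, n_positives = n_pos,
                 n_negatives = n_neg, curves = list(pr = pr, roc = roc)),
            class = "grn_eval")
}

#' @export
print.grn_eval <- function(x, digits = 4, ...) {
  cat("Edge-ranking evaluation\n")
  cat("  positives:", x$n_positives, "  negatives:", x$n_negatives, "\n")
  cat("  AUPR: ", signif(x$aupr, digits),
      "  (random baseline ", signif(x$n_positives /
        (x$n_positives + x$n_negatives), digits), ")\n", sep = "")
  cat("  AUROC:", signif(x$auroc, digits), "\n")
  invisible(x)
}

#' Plot precision-recall and ROC curves of an evaluation
#'
#' @param x A `"grn_eval"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grn_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pr <- x$curves$pr
  graphics::plot(pr$recall, pr$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR (AUPR = %.3f)", x$aupr), ...)
  roc <- x$curves$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' DREAM overall score from AUPR and AUROC p-values
#'
#' \deqn{-\tfrac{1}{2}\log_{10}(p_{AUPR} \cdot p_{AUROC})}
#' where the two p-values are (geometric means of) the probabilities of
#' reaching the observed AUPR and AUROC by chance. Monotone decreasing in
#' each argument.
#'
#' @param p_aupr,p_auroc P-values in `(0, 1]`.
#' @return The overall score (nonnegative real).
#' @examples
#' overall_score(0.01, 0.01)  # 2
#' @export
overall_score <- function(p_aupr, p_auroc) {
  if (!is.numeric(p_aupr) || !is.numeric(p_auroc) ||
      any(p_aupr <= 0) || any(p_aupr > 1) ||
      any(p_auroc <= 0) || any(p_auroc > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  -0.5 * log10(p_aupr * p_auroc)
}

#' Geometric mean of positive values
#'
#' @param x Vector of positive reals.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L || !is.numeric(x) || any(x <= 0)) {
    stop("need a nonempty vector of positive values")
  }
  exp(mean(log(x)))
}

#' Empirical permutation p-values for AUPR and AUROC
#'
#' The official DREAM p-values come from challenge-specific null densities
#' that are not redistributable; this routine estimates p-values offline by
#' permuting which eligible pairs are labelled positive and recomputing both
#' metrics, reporting `(1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @inheritParams evaluate_predictions
#' @param n_perm Number of label permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @return List with `p_aupr`, `p_auroc`, the observed `aupr` and `auroc`,
#'   and `n_perm`.
#' @export
permutation_pvalues <- function(predictions, gold, n_perm = 1000, seed = 1) {
  obs <- evaluate_predictions(predictions, gold)
  if (inherits(predictions, "plsnet")) predictions <- rank_edges(predictions)
  if (!inherits(gold, "gold_standard")) gold <- gold_standard(gold)
  universe <- if (is.null(gold$universe)) .default_universe(gold) else
    gold$universe
  n_pairs <- nrow(universe)
  n_pos <- obs$n_positives
  set.seed(as.integer(seed))
  null_aupr <- numeric(n_perm)
  null_auroc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pos_idx <- sample.int(n_pairs, n_pos)
    g <- gold_standard(universe[pos_idx, , drop = FALSE], universe = universe)
    e <- evaluate_predictions(predictions, g)
    null_aupr[b] <- e$aupr
    null_auroc[b] <- e$auroc
  }
  list(p_aupr = (1 + sum(null_aupr >= obs$aupr)) / (n_perm + 1),
       p_auroc = (1 + sum(null_auroc >= obs$auroc)) / (n_perm + 1),
       aupr = obs$aupr, auroc = obs$auroc, n_perm = n_perm)
}
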