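#' @export
print.plsnet <- function(x, ...) {
  p <- length(x$gene_ids)
  cat("PLS ensemble network inference\n")
  cat("  genes:", p, " regulators:", length(x$regulators), "\n")
  cat("  components:", x$config$ncomp, " candidates/iter:", x$config$ncand,
      " iterations:", x$config$niter, " resample:", x$config$resample, "\n")
  cat("  refined:", isTRUE(attr(x$scores, "refined")),
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Summarize a fitted PLS ensemble network
#'
#' @param object A `"plsnet"` fit.
#' @param top_n Number of top-ranked edges to display.
#' @param ... Unused.
#' @return Invisibly, the ranked edge list.
#' @export
summary.plsnet <- function(object, top_n = 10, ...) {
  print(object)
  nd <- object$diagnostics$n_degenerate
  cat("  degenerate iterations:", sum(nd), "of",
      object$config$niter * length(object$gene_ids), "\n")
  cat("  elapsed:", round(object$diagnostics$elapsed, 2), "s\n\n")
  edges <- rank_edges(object)
  cat("Top", min(top_n, nrow(edges)), "predicted edges:\n")
  print(utils::head(edges, top_n), row.names = FALSE)
  invisible(edges)
}

#' Extract the adjacency-score matrix of a fit
#'
#' @param object A `"plsnet"` fit.
#' @param raw Return the pre-refinement score matrix.
#' @param ... Unused.
#' @return The `p x p` score matrix (rows = regulators, columns = targets).
#' @export
coef.plsnet <- function(object, raw = FALSE, ...) {
  if (raw) object$raw_scores else object$scores
}

#' Plot the ranked edge-score profile of a fit
#'
#' Draws the sorted edge scores on a log-ready axis; a sharp elbow
#' separates confidently predicted regulations from background.
#'
#' @param x A `"plsnet"` fit.
#' @param top_n Number of leading edges to draw (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plsnet <- function(x, top_n = NULL, ...) {
  edges <- rank_edges(x, top_n = top_n)
  graphics::plot(seq_len(nrow(edges)), edges$score, type = "l",
                 xlab = "Edge rank", ylab = "Score",
                 main = "Ranked edge scores", ...)
  invisible(x)
}

#' Grid-search tuning of the ensemble parameters
#'
#' Evaluates every combination of `ncomp_grid` and `ncand_grid` against a
#' gold standard by AUPR (or AUROC) and returns the best setting. Intended
#' for small benchmark networks where a gold standard is available; at
#' genome scale a fixed specification (`ncomp = 5`,
#' `ncand = round(sqrt(p))`) is the practical choice.
#'
#' @inheritParams plsnet
#' @param gold A `"gold_standard"` to score against.
#' @param ncomp_grid,ncand_grid Parameter grids.
#' @param objective `"aupr"` (default) or `"auroc"`.
#' @return List with `best` (a row of the results table) and `results`
#'   (one row per grid point: `ncomp`, `ncand`, `aupr`, `auroc`).
#' @export
plsnet_tune <- function(x, gold, ncomp_grid = 1:5,
                        ncand_grid = c(5, 10, 20, 30), regulators = NULL,
                        niter = 100, seed = 1,
                        objective = c("aupr", "auroc"), ...) {
  objective <- match.arg(objective)
  grid <- expand.grid(ncomp = ncomp_grid, ncand = ncand_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- plsnet(x, regulators = regulators, ncomp = grid$ncomp[i],
                  ncand = grid$ncand[i], niter = niter, seed = seed, ...)
    ev <- evaluate_predictions(fit, gold)
    c(aupr = ev$aupr, auroc = ev$auroc)
  })
  results <- cbind(grid, do.call(rbind, res))
  best <- results[which.max(results[[objective]]), , drop = FALSE]
  list(best = best, results = results)
}
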