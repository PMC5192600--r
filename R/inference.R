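.validate_expression <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (nrow(x) < 3L) stop("need at least 3 conditions (rows)")
  if (ncol(x) < 2L) stop("need at least 2 genes (columns)")
  if (is.null(colnames(x))) colnames(x) <- paste0("G", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) {
    stop("duplicate gene names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  x
}

# Default number of candidate regulators: 30 for small networks, sqrt(p)
# for large ones (threshold p = 200 interpolates the two regimes).
.default_ncand <- function(p) if (p <= 200L) 30L else as.integer(round(sqrt(p)))

# Deterministic per-target seed so results do not depend on the order in
# which target subproblems are scheduled (sequential or parallel).
.target_seed <- function(seed, j) (abs(seed) %% 1000000L) * 2000L + j

.infer_target_core <- function(x, target, eligible, ncomp, ncand, niter,
                               resample, sub_frac, scale, trace = FALSE) {
  n <- nrow(x)
  p <- ncol(x)
  scores <- numeric(p)
  n_degenerate <- 0L
  ops <- 0
  nel <- length(eligible)
  K <- min(ncand, nel)
  sub_n <- max(2L, as.integer(round(sub_frac * n)))
  boot <- resample == "bootstrap"
  trace_log <- if (trace) vector("list", niter) else NULL
  for (it in seq_len(niter)) {
    idx <- if (boot) sample.int(n, n, replace = TRUE) else sample.int(n, sub_n)
    cand <- if (nel > K) eligible[sample.int(nel, K)] else eligible
    xb <- x[idx, cand, drop = FALSE]
    yb <- x[idx, target]
    nb <- length(idx)
    yb <- yb - mean(yb)
    xb <- xb - rep(colMeans(xb), each = nb)
    if (scale) {
      sds <- sqrt(colSums(xb * xb) / (nb - 1L))
      sds[sds == 0] <- 1
      xb <- xb / rep(sds, each = nb)
    }
    m_eff <- min(ncomp, length(cand), nb - 1L)
    fit <- .plsfs_core(xb, yb, m_eff)
    if (is.null(fit)) {
      n_degenerate <- n_degenerate + 1L
      ops <- ops + nb * length(cand)
      if (trace) trace_log[[it]] <- list(cand = cand, vip = numeric(length(cand)))
    } else {
      scores[cand] <- scores[cand] + fit$vip
      ops <- ops + nb * length(cand) * fit$ncomp
      if (trace) trace_log[[it]] <- list(cand = cand, vip = fit$vip)
    }
  }
  scores[target] <- 0
  list(scores = scores, n_degenerate = n_degenerate, ops = ops,
       trace = trace_log)
}

#' Score candidate regulators of a single target gene
#'
#' Runs the randomized PLS ensemble for one target: over `niter` iterations
#' the conditions are resampled, `ncand` candidate regulators are drawn
#' uniformly without replacement from the eligible regulators (all genes, or
#' `regulators`, minus the target itself), a SIMPLS model of the target on
#' the sampled candidates is fitted, and each candidate accumulates its VIP
#' score. Iterations with a degenerate fit contribute nothing and are
#' counted.
#'
#' @param x Expression matrix, conditions x genes, with gene names as column
#'   names.
#' @param target Target gene name (or column index).
#' @param regulators Optional character vector of gene names allowed as
#'   predictors; default all genes.
#' @param ncomp Number of PLS components per fit (clamped to the data).
#' @param ncand Number of candidate regulators per iteration; default 30
#'   when `p <= 200`, else `round(sqrt(p))`.
#' @param niter Number of ensemble iterations.
#' @param resample Row resampling scheme: `"bootstrap"` (n rows drawn with
#'   replacement; default) or `"subsample"` (a fraction `sub_frac` drawn
#'   without replacement).
#' @param sub_frac Subsample fraction when `resample = "subsample"`.
#' @param scale Also scale columns to unit variance within each resample.
#' @param seed Integer seed; the target's stream is derived from it so that
#'   results are reproducible and independent of scheduling order.
#' @return Named nonnegative score vector over all genes (the target and
#'   non-eligible genes score 0), with attributes `n_degenerate` and `ops`
#'   (accumulated work counter, proportional to rows x candidates x
#'   components).
#' @export
infer_target <- function(x, target, regulators = NULL, ncomp = 5,
                         ncand = NULL, niter = 1000,
                         resample = c("bootstrap", "subsample"),
                         sub_frac = 0.8, scale = FALSE, seed = 1) {
  x <- .validate_expression(x)
  resample <- match.arg(resample)
  genes <- colnames(x)
  if (is.character(target)) {
    ti <- match(target, genes)
    if (is.na(ti)) stop("target gene not found: ", target)
  } else {
    ti <- as.integer(target)
    if (ti < 1L || ti > ncol(x)) stop("target index out of range")
  }
  reg_idx <- .resolve_regulators(genes, regulators)
  eligible <- setdiff(reg_idx, ti)
  if (length(eligible) == 0L) {
    stop("no eligible candidate regulators for target ", genes[ti])
  }
  if (is.null(ncand)) ncand <- .default_ncand(ncol(x))
  if (ncand < 1L) stop("`ncand` must be >= 1")
  if (niter < 1L) stop("`niter` must be >= 1")
  set.seed(.target_seed(seed, ti))
  res <- .infer_target_core(x, ti, eligible, as.integer(ncomp),
                            as.integer(ncand), as.integer(niter),
                            resample, sub_frac, scale)
  out <- stats::setNames(res$scores, genes)
  attr(out, "n_degenerate") <- res$n_degenerate
  attr(out, "ops") <- res$ops
  out
}

.resolve_regulators <- function(genes, regulators) {
  if (is.null(regulators)) return(seq_along(genes))
  if (length(regulators) == 0L) stop("`regulators` must be nonempty")
  idx <- match(unique(regulators), genes)
  if (anyNA(idx)) {
    stop("regulator(s) not present in the expression matrix: ",
         paste(unique(regulators)[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Infer a gene regulatory network with a PLS ensemble
#'
#' The network inference problem over `p` genes is decomposed into `p`
#' per-target feature-selection subproblems, each solved by the randomized
#' SIMPLS/VIP ensemble of [infer_target()]. Aggregated VIP scores fill a
#' `p x p` adjacency-score matrix (rows = putative regulators, columns =
#' targets), which is then refined by multiplying each regulator row by its
#' variance ([refine_network()]) so that hub regulators — regulators whose
#' score profile across targets is strongly structured — are promoted.
#'
#' @inheritParams infer_target
#' @param refine Apply the hub-variance row refinement (default `TRUE`).
#' @param threads Number of worker processes for the per-target subproblems
#'   (forked via \pkg{parallel}; results are identical to sequential
#'   execution for a fixed seed).
#' @param trace Keep a per-iteration log of sampled candidates and VIP
#'   contributions (memory-heavy; for diagnostics at small `niter` only).
#' @return An object of class `"plsnet"`: a list with `scores` (the refined
#'   `p x p` matrix; entry `(i, j)` is the inferred strength that gene `i`
#'   regulates gene `j`; diagonal 0), `raw_scores` (before refinement),
#'   `gene_ids`, `regulators`, `config`, and `diagnostics` (per-target
#'   degenerate-iteration counts, work counters, elapsed time).
#' @examples
#' net <- generate_network(p = 10, avg_out_degree = 1.5, seed = 42)
#' expr <- simulate_expression(net, n = 50)
#' fit <- plsnet(expr, ncand = 5, niter = 50, seed = 1)
#' head(rank_edges(fit), 3)
#' @export
plsnet <- function(x, regulators = NULL, ncomp = 5, ncand = NULL,
                   niter = 1000, resample = c("bootstrap", "subsample"),
                   sub_frac = 0.8, scale = FALSE, seed = 1, refine = TRUE,
                   threads = 1, trace = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  x <- .validate_expression(x)
  resample <- match.arg(resample)
  genes <- colnames(x)
  p <- ncol(x)
  reg_idx <- .resolve_regulators(genes, regulators)
  if (is.null(ncand)) ncand <- .default_ncand(p)
  if (!is.numeric(ncand) || ncand < 1L) stop("`ncand` must be >= 1")
  if (!is.numeric(niter) || niter < 1L) stop("`niter` must be >= 1")
  if (!is.numeric(ncomp) || ncomp < 1L) stop("`ncomp` must be >= 1")
  ncomp <- as.integer(ncomp); ncand <- as.integer(ncand)
  niter <- as.integer(niter); seed <- as.integer(seed)

  run_one <- function(ti) {
    eligible <- setdiff(reg_idx, ti)
    if (length(eligible) == 0L) {
      stop("no eligible candidate regulators for target ", genes[ti])
    }
    set.seed(.target_seed(seed, ti))
    .infer_target_core(x, ti, eligible, ncomp, ncand, niter,
                       resample, sub_frac, scale, trace = trace)
  }
  res <- if (threads > 1L) {
    parallel::mclapply(seq_len(p), run_one, mc.cores = threads)
  } else {
    lapply(seq_len(p), run_one)
  }
  err <- vapply(res, inherits, logical(1), "try-error")
  if (any(err)) stop("target subproblem failed: ", genes[which(err)[1]])

  raw <- matrix(0, p, p, dimnames = list(genes, genes))
  for (j in seq_len(p)) raw[, j] <- res[[j]]$scores
  attr(raw, "refined") <- FALSE
  scores <- if (refine) refine_network(raw) else raw

  structure(
    list(scores = scores, raw_scores = raw, gene_ids = genes,
         regulators = genes[reg_idx],
         config = list(ncomp = ncomp, ncand = ncand, niter = niter,
                       resample = resample, sub_frac = sub_frac,
                       scale = scale, seed = seed, refine = refine,
                       threads = as.integer(threads)),
         diagnostics = list(
           n_degenerate = stats::setNames(
             vapply(res, `[[`, integer(1), "n_degenerate"), genes),
           ops = stats::setNames(vapply(res, `[[`, numeric(1), "ops"), genes),
           elapsed = proc.time()[["elapsed"]] - t0),
         trace = if (trace) lapply(res, `[[`, "trace") else NULL),
    class = "plsnet")
}

#' Refine an adjacency-score matrix by regulator-row variance
#'
#' Multiplies each row of the score matrix by the variance of that row's
#' entries: \eqn{W(i,) \leftarrow W(i,) \sigma_i^2}. A regulator whose
#' scores are spread unevenly across targets (a hub driving a few targets
#' strongly) is boosted; a row of constant scores has zero variance and is
#' zeroed out. The variance is the sample variance (denominator count - 1)
#' over the regulator's `p - 1` off-diagonal target scores, structural
#' zeros for never-sampled candidates included; the structural self-score
#' is excluded. Any same-length convention differs only by a constant
#' factor per row and yields the same ranking.
#'
#' Refinement is deliberately single-shot: applying it twice compounds the
#' variance weighting, so a matrix already carrying the `refined` attribute
#' is rejected.
#'
#' @param w Nonnegative square score matrix, rows = regulators, columns =
#'   targets, zero diagonal.
#' @return The refined matrix, with attribute `refined = TRUE`.
#' @export
refine_network <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("score matrix must be square")
  if (any(w < 0)) stop("score matrix must be nonnegative")
  if (any(diag(w) != 0)) stop("score matrix must have a zero diagonal")
  if (isTRUE(attr(w, "refined"))) {
    stop("matrix is already refined; refinement is applied once")
  }
  p <- nrow(w)
  # variance over the p - 1 actual target scores of each regulator; the
  # structural self-score is not part of the row's score profile (a
  # single-target row has no spread: multiplier 0)
  v <- vapply(seq_len(p), function(i) {
    r <- w[i, -i]
    if (length(r) < 2L) 0 else stats::var(r)
  }, numeric(1))
  out <- w * v
  attr(out, "refined") <- TRUE
  out
}

#' Rank predicted regulatory edges
#'
#' Flattens a score matrix (or fitted `"plsnet"` model) into the DREAM
#' prediction format: all admissible regulator-to-target pairs sorted by
#' descending score. Ties are broken by ascending regulator column index,
#' then ascending target index, giving a total deterministic order.
#'
#' @param x A `"plsnet"` fit or a square score matrix with gene names.
#' @param regulators Optional regulator gene names restricting edge sources
#'   (for a `"plsnet"` fit, defaults to the fit's regulator set).
#' @param top_n Optional number of top edges to keep.
#' @return A `data.frame` with columns `regulator`, `target`, `score`,
#'   sorted by decreasing score.
#' @export
rank_edges <- function(x, regulators = NULL, top_n = NULL) {
  if (inherits(x, "plsnet")) {
    if (is.null(regulators)) regulators <- x$regulators
    x <- x$scores
  }
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("score matrix must be square")
  genes <- colnames(x)
  if (is.null(genes)) genes <- paste0("G", seq_len(ncol(x)))
  reg_idx <- .resolve_regulators(genes, regulators)
  if (!is.null(top_n)) {
    if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
      stop("`top_n` must be a positive integer")
    }
  }
  ij <- expand.grid(regulator = reg_idx, target = seq_len(ncol(x)),
                    KEEP.OUT.ATTRS = FALSE)
  ij <- ij[ij$regulator != ij$target, , drop = FALSE]
  sc <- x[cbind(ij$regulator, ij$target)]
  ord <- order(-sc, ij$regulator, ij$target)
  out <- data.frame(regulator = genes[ij$regulator[ord]],
                    target = genes[ij$target[ord]],
                    score = sc[ord], stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- utils::head(out, as.integer(top_n))
  rownames(out) <- NULL
  out
}
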