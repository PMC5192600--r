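#' Generate a random sparse signed regulatory network
#'
#' Each ordered non-self gene pair carries an edge independently with
#' probability `avg_out_degree / (p - 1)`, giving `p * avg_out_degree`
#' expected edges. Edge weights have magnitude uniform in `weight_range`
#' and a random sign. If the spectral radius of the absolute adjacency
#' matrix reaches 1 the weights are rescaled to radius 0.95 so the linear
#' steady state of [simulate_expression()] exists and is stable.
#'
#' @param p Number of genes (>= 2).
#' @param avg_out_degree Expected out-degree per gene (0 <= . <= p - 1).
#' @param weight_range Length-2 numeric, magnitude range of edge weights.
#' @param noise_sd Measurement noise standard deviation used at simulation
#'   time.
#' @param perturbation_sd Standard deviation of the per-gene basal
#'   perturbations driving each simulated condition.
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return Object of class `"grn_network"`: list with `adjacency` (p x p
#'   signed weight matrix, rows = regulators), `gene_ids`, `regulator_set`
#'   (genes with out-degree > 0), `p`, `noise_sd`, `perturbation_sd`,
#'   `seed`.
#' @export
generate_network <- function(p, avg_out_degree = 2,
                             weight_range = c(0.5, 1.5),
                             noise_sd = 0.2, perturbation_sd = 1,
                             seed = 1) {
  if (!is.numeric(p) || p < 2L) stop("`p` must be >= 2")
  p <- as.integer(p)
  if (avg_out_degree < 0) stop("`avg_out_degree` must be >= 0")
  if (avg_out_degree > p - 1L) {
    stop("infeasible density: `avg_out_degree` cannot exceed p - 1")
  }
  if (length(weight_range) != 2L || any(weight_range <= 0)) {
    stop("`weight_range` must be two positive numbers")
  }
  set.seed(as.integer(seed))
  genes <- paste0("G", seq_len(p))
  prob <- avg_out_degree / (p - 1L)
  a <- matrix(0, p, p, dimnames = list(genes, genes))
  mask <- matrix(stats::runif(p * p) < prob, p, p)
  diag(mask) <- FALSE
  ne <- sum(mask)
  if (ne > 0L) {
    w <- stats::runif(ne, min(weight_range), max(weight_range)) *
      sample(c(-1, 1), ne, replace = TRUE)
    a[mask] <- w
    rho <- max(abs(eigen(abs(a), only.values = TRUE)$values))
    if (rho >= 1) a <- a * (0.95 / rho)
  }
  structure(list(adjacency = a, gene_ids = genes,
                 regulator_set = genes[rowSums(a != 0) > 0], p = p,
                 noise_sd = noise_sd, perturbation_sd = perturbation_sd,
                 seed = as.integer(seed)),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Synthetic linear GRN:", x$p, "genes,", sum(x$adjacency != 0),
      "edges,", length(x$regulator_set), "regulators\n")
  cat("  perturbation sd:", x$perturbation_sd, " noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Simulate multifactorial-style steady-state expression data
#'
#' Emulates multifactorial perturbation experiments: in each condition
#' every gene receives an independent basal perturbation
#' `b ~ N(0, perturbation_sd^2)`, the linear network settles to its steady
#' state `x = A^T x + b` (solved exactly as
#' `x = (I - A^T)^{-1} b`), and `N(0, noise_sd^2)` measurement noise is
#' added.
#'
#' @param network A `"grn_network"` from [generate_network()].
#' @param n Number of conditions (rows) to simulate.
#' @param seed Integer seed; defaults to the network's own seed, so the
#'   same network yields the same data.
#' @return Expression matrix, `n` conditions x `p` genes.
#' @export
simulate_expression <- function(network, n, seed = network$seed) {
  stopifnot(inherits(network, "grn_network"))
  if (!is.numeric(n) || n < 1L) stop("`n` must be >= 1")
  n <- as.integer(n)
  a <- network$adjacency
  rho <- if (any(a != 0)) max(abs(eigen(abs(a), only.values = TRUE)$values))
         else 0
  if (rho >= 1) stop("unstable adjacency: spectral radius >= 1")
  set.seed(as.integer(seed))
  p <- network$p
  b <- matrix(stats::rnorm(n * p, sd = network$perturbation_sd), n, p)
  x <- b %*% solve(diag(p) - a)
  if (network$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n * p, sd = network$noise_sd), n, p)
  }
  colnames(x) <- network$gene_ids
  x
}

#' Gold standard implied by a synthetic network
#'
#' Positives are the nonzero adjacency entries (sign ignored); the
#' eligible universe is every non-self pair from a regulator (out-degree
#' > 0) to any gene.
#'
#' @param network A `"grn_network"`.
#' @return A `"gold_standard"` object.
#' @export
as_gold_standard <- function(network) {
  stopifnot(inherits(network, "grn_network"))
  idx <- which(network$adjacency != 0, arr.ind = TRUE)
  positives <- data.frame(regulator = network$gene_ids[idx[, 1]],
                          target = network$gene_ids[idx[, 2]],
                          stringsAsFactors = FALSE)
  universe <- if (length(network$regulator_set)) {
    u <- expand.grid(regulator = network$regulator_set,
                     target = network$gene_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    u[u$regulator != u$target, , drop = FALSE]
  } else {
    NULL
  }
  if (nrow(positives) == 0L) {
    return(structure(list(positives = positives, universe = universe),
                     class = "gold_standard"))
  }
  gold_standard(positives, universe = universe)
}
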