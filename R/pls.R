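#' Center a design matrix and response to zero mean
#'
#' Column-centers a numeric design matrix and centers a response vector,
#' the normalization required before SIMPLS fitting. Optionally scales the
#' design columns to unit sample standard deviation.
#'
#' @param x Numeric matrix, rows = observations (conditions), columns =
#'   features (candidate regulators).
#' @param y Numeric response vector, one entry per row of `x`.
#' @param scale Logical; also divide each column of `x` by its sample
#'   standard deviation (constant columns are left unscaled). Default `FALSE`:
#'   VIP scores are scale-sensitive and the method is defined on centered,
#'   unscaled data.
#' @return A list with components `x` (centered matrix) and `y` (centered
#'   vector).
#' @examples
#' d <- center_xy(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2), c(5, 5, 5))
#' colSums(d$x)  # 0 0
#' d$y           # 0 0 0
#' @export
center_xy <- function(x, y, scale = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric")
  }
  if (nrow(x) != length(y)) {
    stop("dimension mismatch: `x` has ", nrow(x), " rows but `y` has length ",
         length(y))
  }
  if (nrow(x) < 2L) stop("need at least 2 observations")
  xc <- sweep(x, 2L, colMeans(x), "-")
  if (scale) {
    s <- apply(xc, 2L, stats::sd)
    s[s == 0] <- 1
    xc <- sweep(xc, 2L, s, "/")
  }
  list(x = xc, y = y - mean(y))
}

.check_centered <- function(x, y) {
  sx <- max(abs(x))
  if (sx > 0 && max(abs(colMeans(x))) > 1e-8 * sx) {
    stop("`x` must be column-centered (see center_xy())")
  }
  sy <- max(abs(y))
  if (sy > 0 && abs(mean(y)) > 1e-8 * sy) {
    stop("`y` must be centered (see center_xy())")
  }
  invisible(TRUE)
}

# Lean SIMPLS + VIP used inside the ensemble loop. x, y must be centered.
# Returns NULL for a degenerate fit (constant response, zero covariance,
# or no component correlated with the response), otherwise a list with the
# VIP vector and the number of components actually used.
.plsfs_core <- function(x, y, ncomp, tol = 1e-12) {
  p <- ncol(x)
  sy2 <- sum(y * y)
  if (sy2 <= 0) return(NULL)
  s <- crossprod(x, y)
  s0 <- sqrt(sum(s * s))
  if (s0 <= 0) return(NULL)
  V <- matrix(0, p, ncomp)
  psi <- numeric(ncomp)
  Q <- NULL
  k <- 0L
  for (i in seq_len(ncomp)) {
    sd_ <- if (k > 0L) s - Q %*% crossprod(Q, s) else s
    ns <- sqrt(sum(sd_ * sd_))
    if (ns <= tol * s0) break
    v <- sd_ / ns
    t_ <- x %*% v
    st2 <- sum(t_ * t_)
    if (st2 <= 0) break
    r <- sum(t_ * y)
    k <- k + 1L
    V[, k] <- v
    psi[k] <- (r * r) / (st2 * sy2)
    q <- crossprod(x, t_)
    if (!is.null(Q)) q <- q - Q %*% crossprod(Q, q)
    nq <- sqrt(sum(q * q))
    if (nq > 0) Q <- cbind(Q, q / nq)
  }
  if (k == 0L) return(NULL)
  spsi <- sum(psi[seq_len(k)])
  if (spsi <= 0) return(NULL)
  vip <- sqrt(p * as.vector(V[, seq_len(k), drop = FALSE]^2 %*%
                              psi[seq_len(k)]) / spsi)
  list(vip = vip, ncomp = k)
}

#' Fit a SIMPLS partial least squares model with a univariate response
#'
#' Extracts up to `ncomp` projection directions \eqn{v_i} maximizing the
#' squared covariance \eqn{cov^2(Xv_i, y)} subject to \eqn{\|v_i\| = 1} and
#' orthogonality of the component score vectors \eqn{P_i = Xv_i} to all
#' earlier components (the SIMPLS constraint
#' \eqn{v_i^T X^T X v_j = 0, j < i}). Each direction has a deterministic
#' sign: its largest-magnitude entry is positive.
#'
#' Extraction stops early (with `truncated = TRUE`) when the residual
#' covariance drops below `tol` times its initial norm, e.g. for
#' rank-deficient designs, or when a component has zero variance.
#'
#' @param x Centered numeric design matrix (see [center_xy()]).
#' @param y Centered numeric response vector.
#' @param ncomp Number of components to extract; clamped at
#'   `min(ncol(x), nrow(x) - 1)`.
#' @param tol Relative residual-covariance threshold ending extraction.
#' @return An object of class `"simpls"`: a list with `directions` (p x m
#'   matrix of unit-norm columns), `scores` (n x m component score vectors),
#'   `explained` (per-component \eqn{\psi_i = r^2(y, P_i)}, the squared
#'   correlation between the response and each score vector), `coefficients`
#'   (implied regression coefficients of `y` on `x`), `ncomp` (components
#'   extracted), `ncomp_requested`, `truncated`, and `feature_ids`.
#' @seealso [vip()], [plsfs()]
#' @examples
#' set.seed(1)
#' d <- center_xy(matrix(rnorm(40), 10, 4), rnorm(10))
#' fit <- simpls(d$x, d$y, ncomp = 2)
#' colSums(fit$directions^2)            # unit norms
#' crossprod(fit$scores)                # diagonal: orthogonal scores
#' @export
simpls <- function(x, y, ncomp, tol = 1e-12) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop("dimension mismatch: `x` has ", nrow(x), " rows but `y` has length ",
         length(y))
  }
  if (nrow(x) < 2L) stop("need at least 2 observations")
  if (!is.numeric(ncomp) || length(ncomp) != 1L || ncomp < 1) {
    stop("`ncomp` must be a positive integer")
  }
  ncomp <- as.integer(ncomp)
  if (all(x == 0)) stop("degenerate input: design matrix is all zero")
  .check_centered(x, y)
  ncomp_req <- ncomp
  ncomp <- min(ncomp, ncol(x), nrow(x) - 1L)

  p <- ncol(x)
  sy2 <- sum(y * y)
  s <- crossprod(x, y)
  s0 <- sqrt(sum(s * s))
  V <- matrix(0, p, ncomp)
  TT <- matrix(0, nrow(x), ncomp)
  psi <- numeric(ncomp)
  Q <- NULL
  k <- 0L
  if (s0 > 0) {
    for (i in seq_len(ncomp)) {
      sd_ <- if (k > 0L) s - Q %*% crossprod(Q, s) else s
      ns <- sqrt(sum(sd_ * sd_))
      if (ns <= tol * s0) break
      v <- sd_ / ns
      jmax <- which.max(abs(v))
      if (v[jmax] < 0) v <- -v
      t_ <- x %*% v
      st2 <- sum(t_ * t_)
      if (st2 <= 0) break # zero-variance component carries no information
      r <- sum(t_ * y)
      k <- k + 1L
      V[, k] <- v
      TT[, k] <- t_
      psi[k] <- if (sy2 > 0) (r * r) / (st2 * sy2) else 0
      q <- crossprod(x, t_)
      if (!is.null(Q)) q <- q - Q %*% crossprod(Q, q)
      nq <- sqrt(sum(q * q))
      if (nq > 0) Q <- cbind(Q, q / nq)
    }
  }
  V <- V[, seq_len(k), drop = FALSE]
  TT <- TT[, seq_len(k), drop = FALSE]
  psi <- psi[seq_len(k)]
  feature_ids <- colnames(x)
  if (is.null(feature_ids)) feature_ids <- paste0("x", seq_len(p))
  rownames(V) <- feature_ids
  if (k > 0L) {
    beta <- as.vector(V %*% solve(crossprod(TT), crossprod(TT, y)))
  } else {
    beta <- numeric(p)
  }
  names(beta) <- feature_ids
  fit_vals <- as.vector(x %*% beta)
  structure(
    list(directions = V, scores = TT, explained = psi,
         coefficients = beta, fitted.values = fit_vals,
         residuals = y - fit_vals, ncomp = k, ncomp_requested = ncomp_req,
         truncated = k < ncomp_req, feature_ids = feature_ids),
    class = "simpls")
}

#' Explained variation of the response by each PLS component
#'
#' Computes \eqn{\psi_i = r^2(y, P_i)}, the squared Pearson correlation
#' between the response and each component score vector. A component with
#' zero variance has undefined correlation and is assigned 0.
#'
#' @param fit A `"simpls"` model.
#' @param y Centered response vector used for the fit (or any vector of the
#'   same length).
#' @return Numeric vector of per-component values in `[0, 1]`.
#' @export
explained_variation <- function(fit, y) {
  stopifnot(inherits(fit, "simpls"))
  if (nrow(fit$scores) != length(y)) {
    stop("`y` length does not match the number of observations in `fit`")
  }
  apply(fit$scores, 2L, function(t_) {
    if (stats::sd(t_) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(y, t_)^2
  })
}

#' Variable importance in projection (VIP) scores
#'
#' Aggregates the squared direction weights of a fitted SIMPLS model across
#' components, weighting component \eqn{i} by its explained variation
#' \eqn{\psi_i}:
#' \deqn{VIP_j = \sqrt{p \sum_i \psi_i v_{ji}^2 / \sum_i \psi_i}.}
#' With unit-norm directions the squared scores always sum to the feature
#' count \eqn{p}.
#'
#' @param fit A `"simpls"` model.
#' @param y Optional response; when supplied, \eqn{\psi} is recomputed from
#'   `y` instead of taken from the fit.
#' @return Named nonnegative numeric vector, one score per feature, with
#'   attribute `degenerate = TRUE` (and all-zero scores) when no component
#'   correlates with the response (\eqn{\sum_i \psi_i = 0}).
#' @export
vip <- function(fit, y = NULL) {
  stopifnot(inherits(fit, "simpls"))
  psi <- if (is.null(y)) fit$explained else explained_variation(fit, y)
  p <- nrow(fit$directions)
  spsi <- sum(psi)
  if (fit$ncomp == 0L || spsi <= 0) {
    out <- stats::setNames(numeric(p), fit$feature_ids)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- sqrt(p * as.vector(fit$directions^2 %*% psi) / spsi)
  names(out) <- fit$feature_ids
  attr(out, "degenerate") <- FALSE
  out
}

#' PLS-based feature selection for one regression subproblem
#'
#' Convenience composition of [center_xy()], [simpls()] and [vip()]: given
#' raw (uncentered) data it returns one VIP importance score per candidate
#' feature. Degenerate inputs (constant response, all-zero design, or a fit
#' in which no component correlates with the response) yield all-zero
#' scores flagged with attribute `degenerate = TRUE` rather than an error,
#' so that randomized ensemble iterations can skip them.
#'
#' @inheritParams center_xy
#' @param ncomp Number of PLS components (clamped to what the data support).
#' @return Named VIP score vector aligned with `colnames(x)`, with
#'   attributes `degenerate` (logical) and `ncomp_used` (integer).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 5), 100, 5,
#'             dimnames = list(NULL, paste0("G", 1:5)))
#' y <- 2 * x[, 3] + rnorm(100, sd = 0.1)
#' ranked <- sort(plsfs(x, y, ncomp = 1), decreasing = TRUE)
#' names(ranked)[1]  # "G3"
#' @export
plsfs <- function(x, y, ncomp = 5, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop("dimension mismatch: `x` has ", nrow(x), " rows but `y` has length ",
         length(y))
  }
  if (!is.numeric(ncomp) || length(ncomp) != 1L || ncomp < 1) {
    stop("`ncomp` must be a positive integer")
  }
  feature_ids <- colnames(x)
  if (is.null(feature_ids)) feature_ids <- paste0("x", seq_len(ncol(x)))
  d <- center_xy(x, y, scale = scale)
  m_eff <- min(as.integer(ncomp), ncol(x), nrow(x) - 1L)
  fit <- .plsfs_core(d$x, d$y, m_eff)
  if (is.null(fit)) {
    out <- stats::setNames(numeric(ncol(x)), feature_ids)
    attr(out, "degenerate") <- TRUE
    attr(out, "ncomp_used") <- 0L
    return(out)
  }
  out <- stats::setNames(fit$vip, feature_ids)
  attr(out, "degenerate") <- FALSE
  attr(out, "ncomp_used") <- fit$ncomp
  out
}

#' @export
print.simpls <- function(x, ...) {
  cat("SIMPLS fit:", x$ncomp, "component(s) over", nrow(x$directions),
      "feature(s)")
  if (x$truncated) cat(" (truncated from", x$ncomp_requested, "requested)")
  cat("\n")
  if (x$ncomp > 0L) {
    cat("Explained variation psi(Y; t_i):",
        paste(signif(x$explained, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.simpls <- function(object, ...) object$coefficients

#' @export
fitted.simpls <- function(object, ...) object$fitted.values

#' @export
residuals.simpls <- function(object, ...) object$residuals

#' Predict from a SIMPLS fit
#'
#' Projects new (already centered, consistently with the training data)
#' observations through the implied regression coefficients.
#'
#' @param object A `"simpls"` model.
#' @param newdata Numeric matrix with the same columns as the training
#'   design.
#' @param ... Unused.
#' @return Numeric vector of predicted (centered-scale) responses.
#' @export
predict.simpls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$directions)) {
    stop("`newdata` must have ", nrow(object$directions), " columns")
  }
  as.vector(newdata %*% object$coefficients)
}
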