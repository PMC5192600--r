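test_that("centering gives exact zero means and is idempotent", {
  d <- center_xy(matrix(c(1, 2, 3), 3, 1), c(5, 5, 5))
  expect_equal(as.vector(d$x), c(-1, 0, 1))
  expect_equal(d$y, c(0, 0, 0))
  d2 <- center_xy(d$x, d$y)
  expect_equal(d2$x, d$x)
  expect_equal(d2$y, d$y)

  set.seed(11)
  d3 <- center_xy(matrix(rnorm(30), 10, 3), rnorm(10))
  expect_lt(max(abs(colMeans(d3$x))), 1e-12)
  expect_lt(abs(mean(d3$y)), 1e-12)

  expect_error(center_xy(matrix(1:6, 3, 2), 1:4), "dimension mismatch")
})

test_that("first SIMPLS direction is the normalized covariance X'y", {
  set.seed(21)
  for (r in 1:20) {
    d <- random_centered_instance(sample(4:15, 1), sample(2:8, 1))
    fit <- simpls(d$x, d$y, ncomp = 1)
    ref <- crossprod(d$x, d$y)
    ref <- ref / sqrt(sum(ref^2))
    cosang <- abs(sum(fit$directions[, 1] * ref))
    expect_gte(cosang, 1 - 1e-10)
  }
})

test_that("a perfectly explanatory orthonormal column is found exactly", {
  x <- cbind(c(1, 0, -1) / sqrt(2), c(1, -2, 1) / sqrt(6))
  y <- x[, 1]
  fit <- simpls(x, y, ncomp = 1)
  expect_equal(as.vector(abs(fit$directions[, 1])), c(1, 0), tolerance = 1e-12)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)
})

test_that("fitted models satisfy the SIMPLS invariants", {
  set.seed(31)
  for (r in 1:40) {
    n <- sample(5:20, 1); p <- sample(2:8, 1); m <- sample(1:4, 1)
    d <- random_centered_instance(n, p)
    fit <- simpls(d$x, d$y, m)
    expect_gte(fit$ncomp, 1)
    # unit-norm directions
    expect_lt(max(abs(colSums(fit$directions^2) - 1)), 1e-10)
    # sign convention: largest-magnitude weight positive
    for (i in seq_len(fit$ncomp)) {
      v <- fit$directions[, i]
      expect_gt(v[which.max(abs(v))], 0)
    }
    # mutually orthogonal score vectors
    if (fit$ncomp > 1) {
      cp <- crossprod(fit$scores)
      off <- max(abs(cp[upper.tri(cp)]))
      expect_lt(off, 1e-8 * max(diag(cp)))
    }
    # explained variation in [0, 1], cumulative sum non-decreasing
    expect_true(all(fit$explained >= 0 & fit$explained <= 1 + 1e-12))
    expect_true(!is.unsorted(cumsum(fit$explained)))
  }
})

test_that("per-component cov^2 with y matches a deflation-PLS oracle", {
  set.seed(41)
  for (r in 1:40) {
    n <- sample(5:20, 1); p <- sample(2:8, 1); m <- sample(1:4, 1)
    d <- random_centered_instance(n, p)
    fit <- simpls(d$x, d$y, m)
    mine <- apply(fit$scores, 2, function(t_) stats::cov(t_, d$y)^2)
    ref <- oracle_pls_cov2(d$x, d$y, m)
    k <- min(length(mine), length(ref))
    expect_gte(k, 1)
    expect_lt(max(abs(mine[seq_len(k)] - ref[seq_len(k)])), 1e-8)
  }
})

test_that("rank-deficient designs truncate instead of failing", {
  set.seed(51)
  x <- matrix(rnorm(12), 6, 2)
  x <- cbind(x, x[, 1])  # rank 2 with 3 columns
  d <- center_xy(x, rnorm(6))
  fit <- simpls(d$x, d$y, ncomp = 3)
  expect_lte(fit$ncomp, 2)
  expect_true(fit$truncated)
})

test_that("parameter and degenerate-input errors are raised", {
  d <- random_centered_instance(6, 3)
  expect_error(simpls(d$x, d$y, ncomp = 0), "positive integer")
  expect_error(simpls(matrix(0, 5, 3), rnorm(5) - mean(rnorm(5)),
                      ncomp = 1), "degenerate")
  expect_error(simpls(matrix(1:12, 4, 3), rnorm(4), 1), "centered")
})

test_that("explained variation equals the squared sample correlation", {
  set.seed(61)
  d <- random_centered_instance(30, 4)
  fit <- simpls(d$x, d$y, 2)
  # response identical to a component: psi = 1
  t1 <- fit$scores[, 1]
  expect_equal(explained_variation(fit, t1)[1], 1, tolerance = 1e-12)
  # response orthogonal to a centered component: psi = 0
  yo <- rnorm(30)
  yo <- yo - mean(yo)
  yo <- yo - t1 * sum(yo * t1) / sum(t1^2)
  expect_lt(explained_variation(fit, yo)[1], 1e-20)
  # noisy response: matches a direct two-pass correlation formula
  yn <- t1 + rnorm(30, sd = 0.5 * sd(t1))
  direct <- (sum((yn - mean(yn)) * (t1 - mean(t1))))^2 /
    (sum((yn - mean(yn))^2) * sum((t1 - mean(t1))^2))
  expect_equal(explained_variation(fit, yn)[1], direct, tolerance = 1e-12)
})

test_that("VIP closed forms hold: uniform and one-hot weight vectors", {
  # identical columns: the single direction spreads weight uniformly,
  # so every VIP equals 1
  set.seed(71)
  z <- rnorm(20)
  z <- z - mean(z)
  x <- matrix(z, 20, 4)
  fit <- simpls(x, z, ncomp = 1)
  expect_equal(as.vector(vip(fit)), rep(1, 4), tolerance = 1e-10)

  # orthogonal columns, y equal to the first: one-hot direction,
  # VIP = (sqrt(p), 0, ..., 0)
  x2 <- cbind(c(1, 0, -1) / sqrt(2), c(1, -2, 1) / sqrt(6))
  fit2 <- simpls(x2, x2[, 1], ncomp = 1)
  expect_equal(as.vector(vip(fit2)), c(sqrt(2), 0), tolerance = 1e-10)
})

test_that("VIP matches hand-expanded arithmetic for stated psi and weights", {
  # two components with psi = (0.8, 0.2) and fixed unit-norm weights
  v1 <- c(0.6, 0.8, 0)
  v2 <- c(0, 0.6, 0.8)
  fake <- structure(list(directions = cbind(v1, v2), explained = c(0.8, 0.2),
                         scores = matrix(0, 2, 2), ncomp = 2L,
                         feature_ids = c("a", "b", "c")),
                    class = "simpls")
  got <- vip(fake)
  expected <- sqrt(3 * c(0.8 * 0.36,
                         0.8 * 0.64 + 0.2 * 0.36,
                         0.2 * 0.64) / 1.0)
  expect_equal(as.vector(got), expected, tolerance = 1e-12)
  expect_equal(sum(got^2), 3, tolerance = 1e-12)
})

test_that("squared VIP scores sum to the feature count on random fits", {
  set.seed(81)
  for (r in 1:30) {
    n <- sample(6:25, 1); p <- sample(2:8, 1)
    d <- random_centered_instance(n, p)
    fit <- simpls(d$x, d$y, sample(1:4, 1))
    expect_equal(sum(vip(fit)^2), p, tolerance = 1e-8)
  }
})

test_that("plsfs isolates a single informative feature", {
  set.seed(91)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("G", 1:5)))
  y <- 3 * x[, 3]
  s <- plsfs(x, y, ncomp = 1)
  expect_equal(names(which.max(s)), "G3")
  expect_gt(sort(s, decreasing = TRUE)[1], sort(s, decreasing = TRUE)[2])
})

test_that("plsfs treats duplicated and permuted features consistently", {
  set.seed(101)
  x <- matrix(rnorm(40 * 4), 40, 4)
  x <- cbind(x, x[, 2])  # feature 5 duplicates feature 2
  y <- rnorm(40)
  s <- plsfs(x, y, ncomp = 2)
  expect_equal(unname(s[2]), unname(s[5]), tolerance = 1e-10)

  perm <- c(3, 1, 4, 2, 5)
  s_perm <- plsfs(x[, perm], y, ncomp = 2)
  expect_equal(as.vector(s_perm), as.vector(s[perm]), tolerance = 1e-10)
})

test_that("degenerate inputs yield flagged all-zero scores, not errors", {
  set.seed(111)
  x <- matrix(rnorm(30), 10, 3)
  s <- plsfs(x, rep(2, 10), ncomp = 2)   # constant response
  expect_true(attr(s, "degenerate"))
  expect_equal(as.vector(s), c(0, 0, 0))
  s2 <- plsfs(matrix(5, 10, 3), rnorm(10), ncomp = 2)  # constant design
  expect_true(attr(s2, "degenerate"))
  expect_equal(as.vector(s2), c(0, 0, 0))
})

test_that("plsfs has no systematic winner under a pure-noise response", {
  set.seed(121)
  reps <- 200
  p <- 5
  vips <- matrix(0, reps, p)
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(20 * p), 20, p)
    vips[r, ] <- plsfs(x, rnorm(20), ncomp = 2)
  }
  m <- colMeans(vips)
  se <- apply(vips, 2, sd) / sqrt(reps)
  expect_true(all(abs(m - mean(m)) < 3 * se))
})

test_that("simpls regression methods recover a linear signal", {
  set.seed(131)
  x <- matrix(rnorm(50 * 3), 50, 3)
  beta <- c(1, -2, 0.5)
  y <- as.vector(x %*% beta)
  d <- center_xy(x, y)
  fit <- simpls(d$x, d$y, ncomp = 3)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-8)
  expect_equal(fitted(fit), d$y, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_equal(predict(fit, d$x), d$y, tolerance = 1e-8)
})
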