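test_that("noiseless rank-1 structure is recovered exactly", {
  r1 <- rank1_matrix(p = 5L, n = 4L, lambda = 3)
  f <- robust_svd(r1$x, k = 3)
  expect_equal(f$d[1], 3, tolerance = 1e-8)
  expect_equal(abs(f$u[, 1]), r1$u, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(abs(f$v[, 1]), r1$v, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(norm(r1$x - rsvd_approx(f, 1), "F"), 1e-6)
})

test_that("constant matrix gives the closed-form scale c * sqrt(p * n)", {
  x <- matrix(2.5, 6, 5)
  f <- robust_svd(x, k = 3)
  expect_equal(f$d[1], 2.5 * sqrt(30), tolerance = 1e-6)
  expect_true(length(f$d) == 1L || all(f$d[-1] < 1e-6))
})

test_that("unit norms, non-increasing scales, positive-sign convention", {
  set.seed(7)
  x <- outer(runif(20, 2, 6), runif(12, 0.5, 1.5)) + matrix(rnorm(240, 0, 0.3), 20)
  x[sample(240, 30)] <- NA
  f <- robust_svd(x, k = 5)
  expect_equal(colSums(f$u^2), rep(1, ncol(f$u)), tolerance = 1e-8)
  expect_equal(colSums(f$v^2), rep(1, ncol(f$v)), tolerance = 1e-8)
  expect_true(all(diff(f$d) <= 1e-12))
  for (kk in seq_along(f$d))
    expect_gt(f$u[which.max(abs(f$u[, kk])), kk], 0)
})

test_that("fully missing rows and columns are named in errors", {
  x <- matrix(1:20 + 0, 4, 5)
  x[2, ] <- NA
  expect_error(robust_svd(x), "row 2")
  y <- matrix(1:20 + 0, 4, 5)
  y[, 3] <- NA
  expect_error(robust_svd(y), "column 3")
})

test_that("one corrupted cell barely moves the robust fit, unlike classical SVD", {
  r1 <- rank1_matrix(p = 5L, n = 4L, lambda = 3)
  x <- r1$x
  x[2, 2] <- x[2, 2] * 100
  clean_cells <- !(row(x) == 2 & col(x) == 2)
  rob <- rsvd_approx(robust_svd(x, k = 1), 1)
  sv <- svd(x)
  cls <- sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1])
  err_rob <- sqrt(mean((rob - r1$x)[clean_cells]^2))
  err_cls <- sqrt(mean((cls - r1$x)[clean_cells]^2))
  expect_lt(err_rob, err_cls)
  expect_lt(err_rob, 1e-6)
})

test_that("clean complete low-rank fits agree with classical truncated SVD", {
  set.seed(42)
  for (trial in 1:20) {
    p <- sample(20:40, 1)
    n <- sample(10:20, 1)
    base <- outer(runif(p, 3, 9), rep(1, n)) +
      tcrossprod(rnorm(p, 0, 0.5), rnorm(n, 0, 0.5))
    x <- base + matrix(rnorm(p * n, 0, 0.05), p, n)
    f <- robust_svd(x, k = 2)
    rob <- rsvd_approx(f, min(2L, length(f$d)))
    sv <- svd(x)
    cls <- sv$u[, 1:2] %*% (sv$d[1:2] * t(sv$v[, 1:2]))
    rel <- norm(rob - cls, "F") / norm(cls, "F")
    expect_lt(rel, 0.02)
  }
})

test_that("5% gross corruption leaves the robust rank-2 fit nearly intact", {
  set.seed(11)
  wins <- 0L
  for (trial in 1:20) {
    p <- 30L; n <- 15L
    truth <- outer(runif(p, 3, 9), rep(1, n)) +
      tcrossprod(rnorm(p), rnorm(n, 0, 0.4))
    x <- truth
    bad <- sample(p * n, ceiling(0.05 * p * n))
    x[bad] <- x[bad] * 10
    clean <- setdiff(seq_len(p * n), bad)
    f <- robust_svd(x, k = 2)
    rob <- rsvd_approx(f, min(2L, length(f$d)))
    sv <- svd(x)
    cls <- sv$u[, 1:2] %*% (sv$d[1:2] * t(sv$v[, 1:2]))
    rel_rob <- sqrt(sum((rob - truth)[clean]^2)) / sqrt(sum(truth[clean]^2))
    rel_cls <- sqrt(sum((cls - truth)[clean]^2)) / sqrt(sum(truth[clean]^2))
    if (rel_rob < 0.10 && rel_cls > rel_rob) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("rank selection follows the cumulative explained-variation rule", {
  expect_identical(select_rank(c(10, 0, 0), 0.05), 1L)
  expect_identical(select_rank(c(3, 1), 0.05), 2L)  # 9/10 < 0.95
  # brute-force cumulative scan oracle over random spectra
  set.seed(5)
  for (i in 1:50) {
    d <- sort(runif(sample(2:8, 1), 0, 10), decreasing = TRUE)
    alpha <- runif(1, 0.01, 0.3)
    frac <- cumsum(d^2) / sum(d^2)
    oracle <- min(which(frac >= 1 - alpha))
    expect_identical(select_rank(d, alpha), oracle)
  }
  # lambda = (10, 2, 1, 0.5): 100/105.25 = 0.9501 already exceeds 0.95
  expect_identical(select_rank(c(10, 2, 1, 0.5), 0.05), 1L)
  expect_error(select_rank(c(0, 0), 0.05), "zero")
})

test_that("rank selection is monotone in alpha and supports the sum convention", {
  d <- c(10, 4, 2, 1, 0.5)
  rs <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.01), select_rank, 1L, d = d)
  expect_true(all(diff(rs) >= 0))
  expect_identical(select_rank(c(10, 2, 1, 0.5), 0.05, total = "sum"), 3L)
})

test_that("approximation sums the requested components and validates rank", {
  f <- structure(list(u = cbind(c(1, 0, 0)), v = cbind(c(1, 0)), d = 2,
                      iterations = 1L, converged = TRUE,
                      dims = c(p = 3, n = 2)),
                 class = "robust_svd")
  a <- rsvd_approx(f, 1)
  expect_equal(a, matrix(c(2, 0, 0, 0, 0, 0), 3, 2))
  expect_error(rsvd_approx(f, 2), "exceeds")
  expect_error(rsvd_approx(f, 0), "at least 1")

  set.seed(3)
  x <- tcrossprod(matrix(rnorm(40), 10), matrix(rnorm(16), 4)) +
    outer(runif(10, 4, 6), rep(1, 4))
  fit <- robust_svd(x, k = 4)
  errs <- vapply(seq_along(fit$d),
                 function(r) norm(x - rsvd_approx(fit, r), "F"), 0)
  expect_equal(fitted(fit), rsvd_approx(fit, length(fit$d)))
  expect_lt(errs[length(errs)], errs[1] + 1e-9)
})
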