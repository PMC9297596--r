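test_that("log transform has the expected closed forms", {
  expect_equal(log_transform(matrix(0)), matrix(0))
  expect_equal(log_transform(matrix(exp(1) - 1)), matrix(1))
  expect_equal(log_transform(matrix(c(0, exp(2) - 1), 1)), matrix(c(0, 2), 1))
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("median centering removes per-sample location and scale shifts", {
  P <- cbind(rep(3.7, 5), c(1, 2, 3, 2, 2))
  X <- median_center(P)
  expect_equal(X[1, ], rep(0, 5))
  expect_equal(median_center(cbind(c(1, 2, 3)))[1, ], c(-1, 0, 1))

  # scaling a sample's raw counts shifts log depths by ~ln(alpha);
  # centering removes the shift for counts >= 1000
  set.seed(1)
  counts <- matrix(stats::rnbinom(200, size = 50, mu = 5000), 100, 2)
  scaled <- counts
  scaled[, 2] <- round(counts[, 2] * 2.5)
  r1 <- median_center(log_transform(counts))
  r2 <- median_center(log_transform(scaled))
  expect_lt(max(abs(r1[2, ] - r2[2, ])), 0.01)
})

test_that("rank selection follows the cumulative variance rule", {
  set.seed(3)
  # rank-1 matrix: one direction explains everything
  X1 <- outer(stats::rnorm(8), stats::rnorm(40))
  b <- fit_basis(X1, v = 0.90)
  expect_equal(b$per_partition[[1]]$k, 1L)
  expect_lt(max(abs(project_out(X1, b))), 1e-10)

  # singular values {4, 3}: fractions 0.64 then 1.0, so v=0.90 needs k=2
  u <- qr.Q(qr(matrix(stats::rnorm(6 * 2), 6)))
  v <- qr.Q(qr(matrix(stats::rnorm(20 * 2), 20)))
  X2 <- u %*% diag(c(4, 3)) %*% t(v)
  expect_equal(fit_basis(X2, v = 0.90)$per_partition[[1]]$k, 2L)
  expect_equal(fit_basis(X2, v = 0.60)$per_partition[[1]]$k, 1L)

  # v = 1 on a full-rank matrix keeps every direction
  X3 <- matrix(stats::rnorm(6 * 20), 6, 20)
  expect_equal(fit_basis(X3, v = 1)$per_partition[[1]]$k, 6L)

  expect_error(fit_basis(X3[1, , drop = FALSE]), "at least 2")
  expect_error(fit_basis(X3, v = 0), "in \\(0, 1\\]")
})

test_that("rank is non-decreasing in the variance threshold", {
  set.seed(4)
  X <- matrix(stats::rnorm(10 * 60), 10, 60)
  parts <- partition_targets(60, 20)
  ks <- sapply(c(0.3, 0.6, 0.9, 0.99), function(v)
    vapply(fit_basis(X, v, parts)$per_partition, `[[`, integer(1), "k"))
  expect_true(all(apply(ks, 1, function(r) all(diff(r) >= 0))))
})

test_that("projection is idempotent, annihilates its span, and honours k=0", {
  set.seed(5)
  X <- matrix(stats::rnorm(8 * 50), 8, 50)
  b <- fit_basis(X, v = 0.7, partition_targets(50, 25))
  T1 <- project_out(X, b)
  expect_lt(max(abs(project_out(T1, b) - T1)), 1e-10)

  # rows already in the span of V are annihilated
  pp <- b$per_partition[[1]]
  in_span <- matrix(0, 3, 50)
  in_span[, pp$targets] <- matrix(stats::rnorm(3 * pp$k), 3) %*% pp$V
  expect_lt(max(abs(project_out(in_span, b)[, pp$targets])), 1e-10)

  # empty basis (k = 0) leaves the data untouched
  b0 <- b
  for (q in seq_along(b0$per_partition)) {
    b0$per_partition[[q]]$k <- 0L
    b0$per_partition[[q]]$V <-
      b0$per_partition[[q]]$V[0, , drop = FALSE]
  }
  expect_identical(project_out(X, b0), X)

  expect_error(project_out(X[, 1:10], b), "targets")
})

test_that("stored basis rows are orthonormal", {
  set.seed(6)
  X <- matrix(stats::rnorm(12 * 80), 12, 80)
  b <- fit_basis(X, v = 0.95, partition_targets(80, 40))
  for (pp in b$per_partition) {
    expect_lt(max(abs(tcrossprod(pp$V) - diag(pp$k))), 1e-8)
  }
})

test_that("randomized and exact SVD give matching projections", {
  set.seed(7)
  X <- matrix(stats::rnorm(30 * 800), 30, 800) +
    outer(stats::rnorm(30), stats::rnorm(800, sd = 0.5))
  parts <- partition_targets(800, 400)
  te <- project_out(X, fit_basis(X, 0.9, parts, method = "exact"))
  tr <- project_out(X, fit_basis(X, 0.9, parts, method = "randomized",
                                 seed = 99))
  expect_lt(max(abs(te - tr)), 1e-6)
})

test_that("batch factors are removed while sparse CNV signal survives", {
  set.seed(8)
  p <- 30; n <- 400
  noise <- matrix(stats::rnorm(p * n, sd = 0.05), p, n)
  g <- stats::rnorm(p); w <- stats::rnorm(n, sd = 0.3)
  X <- noise + g %o% w
  b <- fit_basis(X, v = 0.90)
  resid <- project_out(X, b)
  # injected rank-1 batch structure is suppressed
  expect_lt(max(abs(cor(t(resid), w)), na.rm = TRUE), 0.05)

  # a sparse spike in a held-out query keeps most of its magnitude
  q <- stats::rnorm(n, sd = 0.05)
  spike_idx <- 101:110
  q[spike_idx] <- q[spike_idx] + log(0.5)
  qr_ <- drop(project_out(matrix(q, 1), b))
  retained <- mean(qr_[spike_idx] - mean(qr_[-spike_idx])) / log(0.5)
  expect_gt(retained, 0.5)
})

test_that("transform_f reproduces training rows and is scale-insensitive", {
  d <- small_depth_fixture(n = 40, p = 8, seed = 11, mean_depth = 2000)
  parts <- partition_targets(40, 20)
  X <- median_center(log_transform(d$counts))
  basis <- fit_basis(X, 0.9, parts)
  T_train <- project_out(X, basis)

  expect_identical(transform_f(d$counts, basis), T_train)

  # doubling all counts of one sample barely changes its transformed row
  doubled <- d$counts[, 3, drop = FALSE] * 2
  row_doubled <- transform_f(doubled, basis)
  expect_lt(max(abs(row_doubled - T_train[3, ])), 0.02)

  # degenerate all-zero query stays finite
  zero <- transform_f(matrix(0, 40, 1), basis)
  expect_true(all(is.finite(zero)))

  expect_error(transform_f(matrix(1, 10, 1), basis), "targets")
})
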