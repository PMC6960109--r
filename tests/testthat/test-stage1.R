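test_that("bpdn_solve handles identity systems and trivially feasible targets", {
  op <- identity_op(2, 2)
  y <- c(1, -2, 0, 3)
  sol <- bpdn_solve(op, y, solver_config(sigma = 0))
  expect_equal(c(t(sol$Z)), y, tolerance = 1e-6)
  expect_true(sol$converged)
  # sigma >= ||y|| makes zero feasible with minimal l1
  sol0 <- bpdn_solve(op, y, solver_config(sigma = sqrt(sum(y^2))))
  expect_equal(sol0$Z, matrix(0, 2, 2))
})

test_that("bpdn_solve finds the minimal-l1 point of a dense system", {
  # A = [[1,0,1],[0,1,1]], y = [1,1]: solutions a = b = 1 - c; |.|_1 is
  # minimised at c = 1 with value 1
  A <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  sol <- bpdn_solve(dense_op(A), c(1, 1), solver_config())
  expect_equal(c(sol$Z), c(0, 0, 1), tolerance = 1e-4)
  expect_equal(sum(abs(sol$Z)), 1, tolerance = 1e-4)
})

test_that("bpdn_solve matches the brute-force linear-programming oracle", {
  set.seed(21)
  for (trial in 1:20) {
    m <- sample(3:4, 1); n <- sample(3:4, 1)
    basis <- dct_basis_pair(m, n)
    mask <- matrix(rbinom(m * n, 1, 0.6), m, n)
    if (sum(mask) < 3 || sum(mask) > 9) mask[] <- rbinom(m * n, 1, 0.5)
    if (sum(mask) == 0) mask[1] <- 1
    op <- build_sensing_operator(mask, basis)
    Ztrue <- matrix(stats::rnorm(m * n) * rbinom(m * n, 1, 0.4), m, n)
    y <- op$apply(Ztrue)
    if (sqrt(sum(y^2)) < 1e-8) next
    sol <- suppressWarnings(bpdn_solve(op, y, solver_config(max_iters = 600)))
    oracle <- min_l1_oracle(materialize_op(op), y)
    expect_lte(sum(abs(sol$Z)), oracle + 1e-4)
    expect_lte(sol$residual_norm, 1e-4 * max(1, sqrt(sum(y^2))))
  }
})

test_that("recover_stage1 interpolates fully observed data and recovers sparse truths", {
  set.seed(13)
  X <- matrix(stats::runif(12 * 10, 1, 5), 12, 10)
  mask <- matrix(1, 12, 10)
  res <- recover_stage1(X, mask, solver_config())
  expect_lt(sqrt(sum((res$X_tilde - X)^2)) / sqrt(sum(X^2)), 1e-6)
  expect_equal(res$X_tilde, inverse_2d(res$Z, dct_basis_pair(12, 10)),
               tolerance = 1e-10)
  # all-zero observed data recovers the zero matrix
  res0 <- recover_stage1(matrix(0, 6, 6), matrix(1, 6, 6), solver_config())
  expect_equal(res0$X_tilde, matrix(0, 6, 6))

  # 25-sparse 32x32 truth at 60% observability: exact-recovery regime
  tr <- sparse_dct_truth(25, 32, seed = 5)
  set.seed(6)
  mask <- matrix(0, 32, 32); mask[sample(1024, round(0.6 * 1024))] <- 1
  rec <- suppressWarnings(recover_stage1(tr$X * mask, mask,
                                         solver_config(max_iters = 500)))
  expect_lt(sqrt(sum((rec$X_tilde - tr$X)^2)) / sqrt(sum(tr$X^2)), 1e-3)
})

test_that("stage-1 recovery is scale-equivariant and improves with observability", {
  tr <- sparse_dct_truth(12, 16, seed = 8)
  set.seed(9)
  mask <- matrix(0, 16, 16); mask[sample(256, 160)] <- 1
  r1 <- suppressWarnings(recover_stage1(tr$X * mask, mask, solver_config()))
  r5 <- suppressWarnings(recover_stage1(5 * tr$X * mask, mask, solver_config()))
  expect_equal(r5$X_tilde, 5 * r1$X_tilde, tolerance = 1e-3)
  # error at 40% observability is no better than at 80%
  err <- sapply(c(0.4, 0.8), function(f) {
    set.seed(11)
    msk <- matrix(0, 16, 16); msk[sample(256, round(f * 256))] <- 1
    r <- suppressWarnings(recover_stage1(tr$X * msk, msk, solver_config()))
    sqrt(sum((r$X_tilde - tr$X)^2))
  })
  expect_lte(err[2], err[1] + 1e-8)
})
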