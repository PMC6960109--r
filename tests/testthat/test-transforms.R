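test_that("dct_matrix produces the orthonormal DCT-II", {
  expect_equal(dct_matrix(1), matrix(1))
  expect_equal(dct_matrix(2),
               matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2, byrow = TRUE))
  expect_equal(dct_matrix(4)[1, ], rep(0.5, 4))
  expect_error(dct_matrix(0))
  expect_error(dct_matrix(-3))
})

test_that("two-sided transforms are mutually inverse isometries", {
  set.seed(3)
  for (dims in list(c(5, 7), c(8, 8), c(1, 6))) {
    basis <- dct_basis_pair(dims[1], dims[2])
    X <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    Z <- forward_2d(X, basis)
    expect_equal(inverse_2d(Z, basis), X, tolerance = 1e-10)
    # Frobenius norm preserved
    expect_equal(sqrt(sum(Z^2)), sqrt(sum(X^2)), tolerance = 1e-10)
  }
  basis <- dct_basis_pair(4, 6)
  expect_equal(forward_2d(matrix(0, 4, 6), basis), matrix(0, 4, 6))
  # constant matrix concentrates in the DC coefficient
  Z <- forward_2d(matrix(2, 4, 6), basis)
  expect_equal(Z[1, 1], 2 * sqrt(24))
  expect_equal(sum(abs(Z)) - abs(Z[1, 1]), 0, tolerance = 1e-12)
  # and back
  Zdc <- matrix(0, 4, 6); Zdc[1, 1] <- sqrt(24)
  expect_equal(inverse_2d(Zdc, basis), matrix(1, 4, 6))
  expect_error(forward_2d(matrix(0, 3, 3), basis), "basis expects")
})

test_that("sensing operator extracts observed entries and honors its adjoint", {
  set.seed(4)
  m <- 5; n <- 6
  basis <- dct_basis_pair(m, n)
  mask <- matrix(rbinom(m * n, 1, 0.6), m, n)
  mask[1, ] <- 1                 # ensure non-empty
  op <- build_sensing_operator(mask, basis)
  expect_equal(op$n_observed, sum(mask))
  # full observation: apply is the row-major vectorisation of the synthesis
  opf <- build_sensing_operator(matrix(1, m, n), basis)
  Z <- matrix(stats::rnorm(m * n), m, n)
  expect_equal(opf$apply(Z), c(t(inverse_2d(Z, basis))))
  # adjoint identity on random pairs
  for (i in 1:20) {
    Z <- matrix(stats::rnorm(m * n), m, n)
    v <- stats::rnorm(op$n_observed)
    lhs <- sum(op$apply(Z) * v)
    rhs <- sum(Z * op$adjoint(v))
    expect_equal(lhs, rhs, tolerance = 1e-8 * max(1, abs(lhs)))
  }
  # masking after an isometry is a contraction
  for (i in 1:10) {
    Z <- matrix(stats::rnorm(m * n), m, n)
    expect_lte(sqrt(sum(op$apply(Z)^2)), sqrt(sum(Z^2)) + 1e-12)
  }
  expect_error(build_sensing_operator(matrix(0, m, n), basis), "no observed")
})

test_that("row-selection pattern on a 6-vector picks entries 1, 3, 6", {
  # identity bases turn the operator into pure row selection
  basis <- structure(list(D_c = diag(6), D_r = diag(1)),
                     class = "dct_basis_pair")
  mask <- matrix(c(1, 0, 1, 0, 0, 1), 6, 1)
  op <- build_sensing_operator(mask, basis)
  x <- matrix(c(10, 20, 30, 40, 50, 60), 6, 1)
  expect_equal(op$apply(x), c(10, 30, 60))
  expect_equal(observed_vector(x, op), c(10, 30, 60))
})

test_that("operator agrees entrywise with a materialised selection x Kronecker matrix", {
  set.seed(9)
  basis <- dct_basis_pair(3, 3)
  mask <- matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3)
  op <- build_sensing_operator(mask, basis)
  A <- materialize_op(op)
  # oracle: row-major vec of t(D_c) Z D_r is (D_c' kron D_r') vecr(Z)
  K <- t(basis$D_c) %x% t(basis$D_r)
  sel <- which(c(t(mask)) == 1)
  expect_equal(A, K[sel, , drop = FALSE], tolerance = 1e-12)
  Z <- matrix(stats::rnorm(9), 3, 3)
  expect_equal(op$apply(Z), as.vector(A %*% c(t(Z))), tolerance = 1e-12)
})
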