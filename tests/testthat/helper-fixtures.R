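# shared helpers: small operators, oracles, and fixture files built in code

# sensing-operator-like wrapper around an explicit dense matrix A (p x q),
# coefficient space laid out as a 1 x q matrix
dense_op <- function(A) {
  list(apply = function(Z) as.vector(A %*% c(Z)),
       adjoint = function(v) matrix(t(A) %*% v, 1, ncol(A)),
       dims = c(1L, ncol(A)), n_observed = nrow(A))
}

# identity operator on an m x n coefficient matrix (row-major vectorisation)
identity_op <- function(m, n) {
  list(apply = function(Z) c(t(Z)),
       adjoint = function(v) t(matrix(v, n, m)),
       dims = c(m, n), n_observed = m * n)
}

# materialise op as a dense |observed| x (m*n) matrix, columns indexed by
# the row-major vectorisation of the coefficient matrix
materialize_op <- function(op) {
  m <- op$dims[1]; n <- op$dims[2]
  cols <- lapply(seq_len(m * n), function(j) {
    Zt <- matrix(0, n, m); Zt[j] <- 1
    op$apply(t(Zt))
  })
  do.call(cbind, cols)
}

# brute-force minimal-l1 value of {z : A z = y} by enumerating supports of
# size nrow(A) (every vertex of the LP lives on such a support)
min_l1_oracle <- function(A, y, tol = 1e-8) {
  p <- nrow(A); q <- ncol(A)
  best <- Inf
  for (S in utils::combn(q, min(p, q), simplify = FALSE)) {
    As <- A[, S, drop = FALSE]
    z <- tryCatch(qr.solve(As, y, tol = 1e-10), error = function(e) NULL)
    if (is.null(z)) next
    if (max(abs(As %*% z - y)) < tol) best <- min(best, sum(abs(z)))
  }
  best
}

# direct confusion-matrix metrics, independent of the package implementation
confusion_metrics <- function(truth, pred) {
  acc <- sum(truth == pred) / length(truth)
  f1w <- 0
  for (cl in unique(truth)) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    pr <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rc <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    f1 <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
    f1w <- f1w + f1 * sum(truth == cl) / length(truth)
  }
  c(accuracy = acc, weighted_f1 = f1w)
}

# a 32 x 32 ground truth with exactly k nonzero low-frequency DCT
# coefficients (used for the exact-recovery regime)
sparse_dct_truth <- function(k = 25, size = 32, seed = 5) {
  basis <- dct_basis_pair(size, size)
  Z <- matrix(0, size, size)
  set.seed(seed)
  pos <- sample.int(100, k)            # within the low-frequency 10x10 block
  Z[cbind((pos - 1) %% 10 + 1, (pos - 1) %/% 10 + 1)] <- stats::rnorm(k, sd = 3)
  list(X = inverse_2d(Z, basis), Z = Z, basis = basis)
}
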