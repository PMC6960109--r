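#' Orthonormal DCT-II matrix
#'
#' Returns the size-by-size type-II discrete cosine transform matrix with
#' orthonormal scaling, so that `D %*% t(D)` is the identity. The first row
#' is constant `1/sqrt(size)`. Orthonormal scaling is required for the
#' analysis-prior and synthesis-prior formulations of the sparse recovery to
#' coincide.
#'
#' @param size Positive integer dimension.
#' @return A `size x size` orthonormal matrix.
#' @examples
#' D <- dct_matrix(4)
#' max(abs(D %*% t(D) - diag(4)))  # ~ 1e-16
#' @export
dct_matrix <- function(size) {
  if (length(size) != 1 || !is.finite(size) || size < 1 || size != floor(size))
    stop("size must be a positive integer")
  n <- as.integer(size)
  k <- seq_len(n) - 1          # frequency index, rows
  j <- seq_len(n) - 1          # position index, columns
  D <- sqrt(2 / n) * cos(outer(k, 2 * j + 1) * pi / (2 * n))
  D[1, ] <- 1 / sqrt(n)
  D
}

#' DCT basis pair for a matrix of given dimensions
#'
#' Bundles the column-wise (`m x m`) and row-wise (`n x n`) orthonormal
#' DCT-II matrices used by the two-sided transforms.
#'
#' @param m Number of rows (subjects).
#' @param n Number of columns (genes).
#' @return A list of class `dct_basis_pair` with elements `D_c` and `D_r`.
#' @export
dct_basis_pair <- function(m, n) {
  structure(list(D_c = dct_matrix(m), D_r = dct_matrix(n)),
            class = "dct_basis_pair")
}

#' Two-sided DCT analysis transform
#'
#' Computes the double-sparsity coefficient matrix `Z = D_c X t(D_r)`:
#' every column and every row of `X` is transformed, so slow variation
#' across both subjects and genes concentrates energy in low-index
#' coefficients.
#'
#' @param X Numeric `m x n` matrix.
#' @param basis A [dct_basis_pair()] with conforming dimensions.
#' @return The `m x n` coefficient matrix.
#' @export
forward_2d <- function(X, basis) {
  check_basis_shape(X, basis)
  basis$D_c %*% X %*% t(basis$D_r)
}

#' Two-sided DCT synthesis transform
#'
#' Inverse of [forward_2d()]: `X = t(D_c) Z D_r`. Exact inverse because the
#' bases are orthonormal.
#'
#' @param Z Numeric `m x n` coefficient matrix.
#' @param basis A [dct_basis_pair()] with conforming dimensions.
#' @return The reconstructed `m x n` matrix.
#' @export
inverse_2d <- function(Z, basis) {
  check_basis_shape(Z, basis)
  t(basis$D_c) %*% Z %*% basis$D_r
}

check_basis_shape <- function(X, basis) {
  stopifnot(inherits(basis, "dct_basis_pair"))
  if (nrow(X) != nrow(basis$D_c) || ncol(X) != nrow(basis$D_r))
    stop("matrix is ", nrow(X), "x", ncol(X), " but basis expects ",
         nrow(basis$D_c), "x", nrow(basis$D_r))
  invisible(TRUE)
}

#' Validate an observation mask
#'
#' @param mask Binary `m x n` matrix, 1 = observed, 0 = missing.
#' @param require_column_coverage Require at least one observed entry per
#'   column (needed by the denoiser's column statistics).
#' @return The mask, invisibly, after checks.
#' @export
validate_mask <- function(mask, require_column_coverage = TRUE) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
  if (all(mask == 0)) stop("mask has no observed entries")
  if (require_column_coverage && any(colSums(mask) == 0))
    stop("column(s) with no observed entry: ",
         paste(utils::head(which(colSums(mask) == 0), 5), collapse = ", "))
  invisible(mask)
}

#' Masked DCT sensing operator and its adjoint
#'
#' Builds the matrix-free linear map at the heart of the compressive-sensing
#' recovery: `apply(Z)` synthesises `t(D_c) Z D_r` and extracts the entries
#' at observed mask positions in a fixed row-major scan order;
#' `adjoint(v)` embeds a data vector back at the observed positions (zero
#' elsewhere) and analyses it with `D_c . D_r^T`. The pair satisfies the
#' adjoint identity `<apply(Z), v> == <Z, adjoint(v)>`. The operator is
#' never materialised as a dense selection matrix.
#'
#' @param mask Binary observation mask (`m x n`, 1 = observed).
#' @param basis A [dct_basis_pair()] of matching dimensions.
#' @return A list of class `sensing_operator` with functions `apply` and
#'   `adjoint`, plus `mask`, `basis`, `n_observed`, and `dims`.
#' @export
build_sensing_operator <- function(mask, basis) {
  mask <- validate_mask(mask, require_column_coverage = FALSE)
  check_basis_shape(mask, basis)
  # row-major scan order: transpose so R's column-major which() walks rows
  obs_rowmajor <- which(t(mask) == 1)
  m <- nrow(mask); n <- ncol(mask)
  apply_fn <- function(Z) {
    X <- t(basis$D_c) %*% Z %*% basis$D_r
    t(X)[obs_rowmajor]
  }
  adjoint_fn <- function(v) {
    Xt <- matrix(0, n, m)
    Xt[obs_rowmajor] <- v
    basis$D_c %*% t(Xt) %*% t(basis$D_r)
  }
  structure(list(apply = apply_fn, adjoint = adjoint_fn, mask = mask,
                 basis = basis, n_observed = length(obs_rowmajor),
                 dims = c(m, n)),
            class = "sensing_operator")
}

#' Extract the observed data vector for a sensing operator
#'
#' Vectorises the observed entries of a (zero-filled) data matrix in the
#' same row-major scan order the operator uses, producing the compressed
#' measurement vector the solver fits.
#'
#' @param Y Numeric matrix (missing entries zero-filled).
#' @param op A [build_sensing_operator()] result.
#' @return Numeric vector of length `op$n_observed`.
#' @export
observed_vector <- function(Y, op) {
  stopifnot(inherits(op, "sensing_operator"))
  if (!all(dim(Y) == op$dims)) stop("Y dimensions do not match operator")
  t(Y)[which(t(op$mask) == 1)]
}
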