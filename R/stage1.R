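#' Stage 1: compressive-sensing recovery of a masked expression matrix
#'
#' Treats the observed entries of a zero-filled expression matrix as
#' compressed measurements of an underlying matrix that is sparse in the
#' two-sided DCT domain, and recovers that matrix by basis-pursuit denoise:
#' the coefficient matrix `Z` minimising `||Z||_1` subject to the observed
#' entries of `t(D_c) Z D_r` matching the data within `cfg$sigma` is found
#' with [bpdn_solve()], and the estimate is its synthesis
#' `X_tilde = t(D_c) Z D_r`.
#'
#' @param Y An [expression_matrix()] or plain numeric matrix, zero-filled at
#'   missing positions.
#' @param mask Binary observation mask (1 = observed).
#' @param cfg A [solver_config()].
#' @return A list of class `stage1_result` with `X_tilde`, `Z`,
#'   `residual_norm` (l2 misfit on observed entries), `iterations`,
#'   `converged`.
#' @examples
#' X <- matrix(5, 6, 6)             # constant matrix: one DCT coefficient
#' mask <- matrix(rbinom(36, 1, 0.6), 6, 6)
#' res <- recover_stage1(X * mask, mask)
#' max(abs(res$X_tilde - X))        # recovered from partial observation
#' @export
recover_stage1 <- function(Y, mask, cfg = solver_config()) {
  vals <- if (inherits(Y, "expression_matrix")) Y$values else as.matrix(Y)
  mask <- validate_mask(mask, require_column_coverage = FALSE)
  if (!all(dim(vals) == dim(mask))) stop("Y and mask dimensions differ")
  vals <- vals * mask                     # enforce zero-fill at missing
  basis <- dct_basis_pair(nrow(vals), ncol(vals))
  op <- build_sensing_operator(mask, basis)
  y <- observed_vector(vals, op)
  sol <- bpdn_solve(op, y, cfg)
  structure(list(X_tilde = inverse_2d(sol$Z, basis), Z = sol$Z,
                 residual_norm = sol$residual_norm,
                 iterations = sol$iterations, converged = sol$converged),
            class = "stage1_result")
}
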