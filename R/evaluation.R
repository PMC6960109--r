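#' Normalised mean squared error between original and recovered matrices
#'
#' `NMSE = ||X - X_hat||_F^2 / ||X||_F^2`, computed over all entries.
#'
#' @param X_original Ground-truth matrix (must have nonzero Frobenius norm).
#' @param X_recovered Recovered matrix of the same dimensions.
#' @return A non-negative scalar.
#' @examples
#' nmse(matrix(c(3, 4), 1), matrix(c(3, 0), 1))  # 16/25 = 0.64
#' @export
nmse <- function(X_original, X_recovered) {
  X_original <- as.matrix(X_original); X_recovered <- as.matrix(X_recovered)
  if (!all(dim(X_original) == dim(X_recovered)))
    stop("matrices have different dimensions")
  denom <- sum(X_original^2)
  if (denom == 0) stop("original matrix has zero Frobenius norm")
  sum((X_original - X_recovered)^2) / denom
}

#' Draw a random observation mask with an exact observed count
#'
#' Places exactly `round(observed_fraction * m * n)` ones uniformly at
#' random (without replacement). If a draw leaves any column with no
#' observed entry — which the denoiser's column statistics cannot handle —
#' the draw is rejected and redone (with a message).
#'
#' @param m,n Mask dimensions.
#' @param observed_fraction Fraction of observed entries, in (0, 1].
#' @param seed Integer seed; the same seed yields the same mask.
#' @return Binary `m x n` matrix.
#' @export
random_mask <- function(m, n, observed_fraction, seed = 1L) {
  if (observed_fraction <= 0 || observed_fraction > 1)
    stop("observed_fraction must be in (0, 1]")
  k <- round(observed_fraction * m * n)
  if (k < n) stop("observed_fraction too small to cover every column")
  with_local_seed(seed, {
    repeat {
      mask <- matrix(0, m, n)
      mask[sample.int(m * n, k)] <- 1
      if (all(colSums(mask) > 0)) break
      message("random_mask: redraw (a column had no observed entry)")
    }
    mask
  })
}

#' Random-masking imputation experiment
#'
#' The evaluation protocol: for each observed fraction and repeat, entries
#' of a fully observed ground-truth matrix are dropped uniformly at random,
#' the incomplete matrix is imputed under each requested ablation arm, and
#' the NMSE against the truth is recorded. Reported NMSE per
#' (fraction, mode) is the mean over repeats; the reference protocol
#' averages 30 repeats over fractions 0.1 to 0.9 in steps of 0.1.
#'
#' @param X Fully observed ground-truth matrix (or [expression_matrix()]).
#' @param fractions Observed fractions to test (default `seq(0.1, 0.9, 0.1)`).
#' @param n_repeats Repeats per fraction (default 30).
#' @param modes Character vector of ablation arms among
#'   `"dsnn"`, `"stage1"`, `"stage2"`.
#' @param cfg A [dsnn_config()]; its seed drives every mask draw and
#'   denoiser initialisation through derived streams.
#' @return A list with `records` (long-format data.frame: observed_fraction,
#'   repeat_index, mode, nmse) and `summary` (mean NMSE per fraction and
#'   mode).
#' @export
run_masking_experiment <- function(X, fractions = seq(0.1, 0.9, by = 0.1),
                                   n_repeats = 30,
                                   modes = c("dsnn", "stage1", "stage2"),
                                   cfg = dsnn_config()) {
  vals <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  stopifnot(all(modes %in% c("dsnn", "stage1", "stage2")))
  rows <- vector("list", length(fractions) * n_repeats * length(modes))
  i <- 0L
  for (f_idx in seq_along(fractions)) {
    f <- fractions[f_idx]
    for (rep_idx in seq_len(n_repeats)) {
      mask_seed <- derive_seed(cfg$seed, f_idx * 1000L + rep_idx)
      mask <- random_mask(nrow(vals), ncol(vals), f, seed = mask_seed)
      Y <- vals * mask
      for (mode in modes) {
        run_cfg <- cfg
        run_cfg$mode <- mode
        run_cfg$seed <- mask_seed
        X_hat <- dsnn_impute(Y, mask, run_cfg)
        i <- i + 1L
        rows[[i]] <- data.frame(observed_fraction = f,
                                repeat_index = rep_idx,
                                mode = mode,
                                nmse = nmse(vals, X_hat))
      }
    }
  }
  records <- do.call(rbind, rows)
  summary <- stats::aggregate(nmse ~ observed_fraction + mode, records, mean)
  summary <- summary[order(summary$mode, summary$observed_fraction), ]
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
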