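#' Specification of a synthetic expression-like matrix
#'
#' Describes a ground-truth matrix with the two structural properties the
#' imputation method assumes of gene-expression data: low rank (genes act
#' in correlated programs) and sparsity in the two-sided DCT domain with
#' energy concentrated at low frequencies (expression varies slowly across
#' ordered samples and genes).
#'
#' @param m,n Dimensions (subjects by genes).
#' @param rank Target numerical rank of the truth (including the constant
#'   baseline component).
#' @param dct_sparsity Fraction of nonzero 2-D DCT coefficients, in (0, 1].
#' @param noise_sd Additive Gaussian noise standard deviation on the
#'   observed matrix (expression units).
#' @param class_shift Optional mean offset applied to a labelled half of
#'   the rows (on a subset of genes) to create a two-class structure;
#'   `0` disables labels.
#' @param baseline Constant baseline expression level (kept high enough
#'   that the truth is non-negative).
#' @param fluct_sd Per-entry standard deviation of the structured
#'   fluctuation around the baseline, in expression units; the rank-1
#'   factor terms are rescaled to hit this level exactly.
#' @param factor_decay Geometric decay of the amplitude across the
#'   `rank - 1` fluctuation factors (scree-like spectrum, as in real
#'   expression data where a few expression programs dominate).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m, n, rank = 5, dct_sparsity = 0.9,
                           noise_sd = 0.1, class_shift = 0,
                           baseline = 5, fluct_sd = 1.5,
                           factor_decay = 0.75, seed = 1L) {
  stopifnot(m >= 1, n >= 1, rank >= 1, rank <= min(m, n),
            dct_sparsity > 0, dct_sparsity <= 1, noise_sd >= 0,
            baseline >= 0, fluct_sd >= 0,
            factor_decay > 0, factor_decay <= 1)
  structure(list(m = as.integer(m), n = as.integer(n),
                 rank = as.integer(rank), dct_sparsity = dct_sparsity,
                 noise_sd = noise_sd, class_shift = class_shift,
                 baseline = baseline, fluct_sd = fluct_sd,
                 factor_decay = factor_decay, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample an index set of given size biased towards low indices
# (geometric decay of inclusion weight), always including index 1
low_freq_support <- function(size, total, decay = 0.15) {
  w <- exp(-decay * (seq_len(total) - 1))
  unique(c(1L, sample.int(total, size = min(size, total), prob = w)))
}

#' Generate a synthetic expression-like matrix
#'
#' The truth is built in the 2-D DCT coefficient domain as a rank-limited
#' outer-product sum `Z = sum_k c_k u_k v_k'` of sparse factor vectors
#' whose supports are biased to low frequencies and whose amplitudes
#' `c_k` decay geometrically (a scree-like singular spectrum), plus a
#' dominant DC term that encodes a constant expression baseline. The
#' fluctuation part is rescaled so its per-entry standard deviation equals
#' `fluct_sd`. The ground truth is the DCT synthesis of `Z`, shifted (via
#' the DC coefficient) to be non-negative; the observed matrix adds
#' i.i.d. Gaussian noise. With `class_shift > 0`, half the rows receive a
#' mean offset on a quarter of the genes and two-class labels are
#' returned.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (noisy observed [expression_matrix()]),
#'   `truth` (noise-free ground-truth matrix), `labels` (character vector
#'   or `NULL`), and `coefficients` (the DCT coefficient matrix of the
#'   truth before the non-negativity shift).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    m <- spec$m; n <- spec$n
    basis <- dct_basis_pair(m, n)
    Z <- matrix(0, m, n)
    n_fluct <- spec$rank - 1L
    if (n_fluct > 0 && spec$fluct_sd > 0) {
      # split the coefficient budget across rank-1 sparse factors
      target_nnz <- max(n_fluct, ceiling(spec$dct_sparsity * m * n))
      per_factor <- max(1, floor(sqrt(target_nnz / n_fluct)))
      for (k in seq_len(n_fluct)) {
        su <- low_freq_support(per_factor, m)
        sv <- low_freq_support(max(1, floor(target_nnz / (n_fluct * length(su)))), n)
        u <- numeric(m); v <- numeric(n)
        u[su] <- stats::rnorm(length(su))
        v[sv] <- stats::rnorm(length(sv))
        Z <- Z + spec$factor_decay^(k - 1) * outer(u, v)
      }
      Xf <- inverse_2d(Z, basis)
      Z <- Z * spec$fluct_sd / max(stats::sd(Xf), .Machine$double.eps)
    }
    Z[1, 1] <- Z[1, 1] + spec$baseline * sqrt(m * n)  # DC = baseline
    X0 <- inverse_2d(Z, basis)
    shift <- max(0, -min(X0))
    truth <- X0 + shift                          # rank unchanged: DC shift
    labels <- NULL
    if (spec$class_shift > 0) {
      half <- seq_len(floor(m / 2))
      genes <- sample.int(n, max(1, floor(n / 4)))
      truth[half, genes] <- truth[half, genes] + spec$class_shift
      labels <- ifelse(seq_len(m) %in% half, "case", "control")
    }
    observed <- truth + if (spec$noise_sd > 0)
      matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n) else 0
    observed <- pmax(observed, 0)                # raw intensities are >= 0
    list(matrix = expression_matrix(observed),
         truth = truth, labels = labels, coefficients = Z)
  })
}

#' Standard synthetic fixture specifications
#'
#' The three desk-scale fixtures used throughout the test suite:
#' `exact` — 32 x 32 with about 25 nonzero DCT coefficients and no noise
#' (the exact-recovery regime for the compressive-sensing stage);
#' `noisy` — 100 x 200, rank 5, a dense low-frequency-concentrated DCT
#' spectrum (50\% support) and noise sd 0.1 — the standard evaluation
#' fixture, emulating compressible rather than exactly sparse data;
#' `two_class` — 60 x 50, rank 4, class shift 1.5 (the classification
#' fixture).
#'
#' @param name One of `"exact"`, `"noisy"`, `"two_class"`.
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
fixture_spec <- function(name = c("exact", "noisy", "two_class"), seed = 101L) {
  name <- match.arg(name)
  switch(name,
    exact = synthetic_spec(32, 32, rank = 5, dct_sparsity = 25 / 1024,
                           noise_sd = 0, baseline = 5, fluct_sd = 1.5,
                           factor_decay = 0.8, seed = seed),
    noisy = synthetic_spec(100, 200, rank = 5, dct_sparsity = 0.9,
                           noise_sd = 0.1, baseline = 5, fluct_sd = 2.5,
                           factor_decay = 0.75, seed = seed),
    two_class = synthetic_spec(60, 50, rank = 4, dct_sparsity = 0.9,
                               noise_sd = 0.1, class_shift = 1.5,
                               baseline = 5, fluct_sd = 1,
                               factor_decay = 0.75, seed = seed))
}

#' Write the standard fixture suite to a directory
#'
#' Writes the three [fixture_spec()] matrices as TSV (via
#' [write_matrix()]), the two-class labels as a two-column TSV, and a
#' small metadata file recording the generating parameters. Regeneration
#' with the same seed is idempotent.
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed shared by the three fixtures.
#' @return Invisibly, the vector of file paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 101L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- character(0)
  for (nm in c("exact", "noisy", "two_class")) {
    spec <- fixture_spec(nm, seed = seed)
    gen <- generate_matrix(spec)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_matrix(gen$matrix, p)
    paths <- c(paths, p)
    meta <- c(meta, sprintf("%s\tm=%d n=%d rank=%d dct_sparsity=%g noise_sd=%g seed=%d",
                            nm, spec$m, spec$n, spec$rank, spec$dct_sparsity,
                            spec$noise_sd, spec$seed))
    if (!is.null(gen$labels)) {
      lp <- file.path(out_dir, paste0(nm, "_labels.tsv"))
      utils::write.table(data.frame(gen$matrix$sample_ids, gen$labels),
                         lp, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths <- c(paths, lp)
    }
  }
  mp <- file.path(out_dir, "fixtures_meta.tsv")
  writeLines(meta, mp)
  invisible(c(paths, mp))
}
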