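# dsnn

Two-stage imputation of missing values in gene-expression matrices, for
transcriptomics analysts working with microarray (or other bulk
expression) data in which a fraction of entries is missing — from a few
per cent up to 90%. Downstream analyses such as normal-versus-cancer
classification or driver-gene ranking degrade badly on incomplete
matrices; re-hybridising arrays is expensive, so the missing entries are
recovered computationally.

## Method

The package implements the DSNN method (Doubly Sparse DCT domain with
Nuclear Norm minimization). Expression matrices are treated as
subjects-by-genes matrices `Y` (m × n) with a binary observation mask
`Φ`. Two structural properties of expression data drive the recovery:
expression varies slowly across correlated genes and samples, so the
matrix is sparse in the two-sided discrete cosine transform domain; and
genes act in a limited number of co-expression programs, so the matrix is
approximately low-rank.

**Stage 1 — compressive-sensing recovery.** The observed entries are
modelled as compressed measurements of a coefficient matrix `Z` that is
sparse in the orthonormal 2-D DCT basis:

    min ||Z||_1   s.t.   || Φ ∘ (D_cᵀ Z D_r) − Y ||_F ≤ σ

with `D_c`, `D_r` orthonormal DCT-II matrices. The problem is solved
matrix-free by a spectral projected-gradient basis-pursuit solver with
Newton root-finding on the Pareto curve (σ = 0 by default), and the
Stage-1 estimate is the synthesis `X̃ = D_cᵀ Z D_r`.

**Stage 2 — nuclear-norm denoising.** `X̃` is treated as a noisy version
of the truth. Imputed entries deviating from their gene's observed
statistics by at least `λ2` standard deviations (default 0.2) are zeroed,
re-initialised uniformly at random, and repainted by a Split-Bregman
singular-value-thresholding loop with threshold `λ3` (default 100),
which re-imposes retained entries each iteration and converges to a
low-rank-consistent completion.

The package also implements the evaluation protocol used to validate the
method: random masking at observed fractions 0.1–0.9, NMSE
(`||X − X̂||_F² / ||X||_F²`) averaged over repeats, stage-wise ablation,
and a classification harness (KNN k = 3 and linear SVM over PCA,
chi-square and mutual-information feature reduction with stratified
5-fold cross-validation) that measures how much imputation restores
class-discriminative signal. A synthetic generator produces
expression-like low-rank, DCT-compressible fixtures so everything runs
without downloads.

## Worked example

```r
library(dsnn)

# an expression-like 100 x 200 matrix with noise, and a 50%-observed copy
gen  <- generate_matrix(fixture_spec("noisy", seed = 101))
X    <- gen$matrix$values
mask <- random_mask(nrow(X), ncol(X), 0.5, seed = 11)

imputed <- dsnn_impute(X * mask, mask, dsnn_config(seed = 11))
nmse(X, imputed)
#> [1] 0.0004308412

# ablation: each stage alone
nmse(X, dsnn_impute(X * mask, mask, dsnn_config(mode = "stage1", seed = 11)))
#> [1] 0.001553047
attr(imputed, "dsnn_log")$zeroed_fraction
#> [1] 0.40615
```

The two-stage estimate recovers the half-masked matrix to a normalised
mean squared error of about 4 × 10⁻⁴ — roughly 3.5-fold better than the
compressive-sensing stage alone — after screening and repainting about
41% of entries as unreliable imputations.

A command-line interface wrapping these functions (impute / evaluate /
classify / simulate) ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dsnn.R", package = "dsnn"))')" \
    impute --input X.tsv --output Xhat.tsv --mode dsnn --seed 1
```

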