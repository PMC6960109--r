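#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the ground truth.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
accuracy_score <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  if (length(truth) == 0) stop("empty label vectors")
  mean(as.character(truth) == as.character(predicted))
}

#' Class-support-weighted F1 score
#'
#' Per-class F1 = 2 * precision * recall / (precision + recall) (defined as
#' 0 when precision and recall are both 0), averaged with weights
#' proportional to each class's support in the truth vector. The weighting
#' accounts for label imbalance such as unequal tumour and normal counts.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
weighted_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Univariate chi-square feature scores
#'
#' Scores each (non-negative) feature against a class vector by treating
#' per-class feature sums as observed counts and class frequencies times
#' the feature total as expected counts — the standard chi-square filter
#' used for feature selection on frequency-like data. Features are shifted
#' by their minimum first so that imputed matrices containing small
#' negatives remain scoreable.
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels, length `nrow(X)`.
#' @return Numeric vector of `ncol(X)` scores (higher = more informative).
#' @export
chi_square_scores <- function(X, y) {
  X <- as.matrix(X)
  mins <- apply(X, 2, min)
  X <- sweep(X, 2, pmin(mins, 0))         # min-shift negative features
  y <- as.factor(y)
  cls <- levels(y)
  observed <- t(rowsum(X, y))             # features x classes sums
  feat_tot <- rowSums(observed)
  prior <- as.numeric(table(y)[cls]) / length(y)
  expected <- outer(feat_tot, prior)
  sc <- rowSums(ifelse(expected > 0, (observed - expected)^2 / expected, 0))
  sc[feat_tot == 0] <- 0
  unname(sc)
}

#' Univariate mutual-information feature scores
#'
#' Estimates the mutual information between each feature and the class
#' labels after equal-frequency discretisation of the feature into
#' `n_bins` bins.
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels, length `nrow(X)`.
#' @param n_bins Number of quantile bins.
#' @return Numeric vector of `ncol(X)` scores in nats.
#' @export
mutual_info_scores <- function(X, y, n_bins = 5) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X)
  apply(X, 2, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(0)
    bx <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(bx, y) / n
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      p <- tab[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
    mi
  })
}

# fit feature reduction on training data only, apply to both partitions
reduce_features <- function(X_train, X_test, y_train, method, k) {
  k <- min(k, ncol(X_train))
  if (method == "pca") {
    k <- min(k, nrow(X_train) - 1)
    pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE, rank. = k)
    list(train = pc$x[, seq_len(k), drop = FALSE],
         test = stats::predict(pc, X_test)[, seq_len(k), drop = FALSE])
  } else {
    sc <- switch(method,
                 chi_square = chi_square_scores(X_train, y_train),
                 mutual_info = mutual_info_scores(X_train, y_train),
                 stop("unknown feature method: ", method))
    idx <- order(sc, decreasing = TRUE)[seq_len(k)]
    list(train = X_train[, idx, drop = FALSE],
         test = X_test[, idx, drop = FALSE])
  }
}

fit_predict <- function(X_train, y_train, X_test, classifier) {
  y_train <- factor(y_train)
  if (classifier == "knn3") {
    as.character(class::knn(X_train, X_test, y_train, k = 3))
  } else if (classifier == "linear_svm") {
    fit <- e1071::svm(X_train, y_train, kernel = "linear", scale = FALSE)
    as.character(stats::predict(fit, X_test))
  } else stop("unknown classifier: ", classifier)
}

# stratified fold assignment: each class's indices are shuffled and dealt
# round-robin into n_folds folds
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# pick the feature count from the grid by inner 3-fold CV on training data
select_grid_value <- function(X_train, y_train, method, classifier, grid) {
  grid <- unique(pmin(grid, if (method == "pca")
    min(ncol(X_train), nrow(X_train) - 2) else ncol(X_train)))
  grid <- grid[grid >= 1]
  if (length(grid) <= 1) return(grid[1])
  inner <- stratified_folds(y_train, 3)
  acc <- vapply(grid, function(k) {
    mean(vapply(1:3, function(f) {
      tr <- inner != f; te <- !tr
      if (length(unique(y_train[tr])) < 2) return(NA_real_)
      red <- reduce_features(X_train[tr, , drop = FALSE],
                             X_train[te, , drop = FALSE], y_train[tr],
                             method, k)
      accuracy_score(y_train[te],
                     fit_predict(red$train, y_train[tr], red$test, classifier))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]
}

#' Normal-versus-cancer classification validation
#'
#' Quantifies how much imputation helps downstream analysis: at each
#' sampling ratio a random mask is drawn, the matrix is imputed, and
#' two-class classification is run on each matrix arm (`"observed"` =
#' zero-filled incomplete matrix, `"recovered"` = imputed, `"original"` =
#' ground truth) with each feature-reduction method (PCA, chi-square,
#' mutual information; the number of retained features/components is
#' grid-searched on training folds only) and each classifier (KNN with
#' k = 3 and a linear SVM). Metrics are averaged over `n_repeats`
#' re-shufflings of stratified 5-fold cross-validation.
#'
#' @param X Fully observed samples-by-genes matrix (or
#'   [expression_matrix()]).
#' @param labels Two-class label vector aligned to rows of `X`.
#' @param ratios Sampling (observed) ratios to test.
#' @param arms Matrix arms among `"observed"`, `"recovered"`, `"original"`.
#' @param cfg A [dsnn_config()] used for the imputation of the recovered
#'   arm and to seed mask draws and fold shuffles.
#' @param feature_methods Subset of `c("pca", "chi_square", "mutual_info")`.
#' @param classifiers Subset of `c("knn3", "linear_svm")`.
#' @param n_repeats Cross-validation re-shuffles to average (default 20).
#' @param n_folds Folds (default 5); every class must have at least
#'   `n_folds` samples.
#' @param feature_grid Candidate retained-feature counts for the selection
#'   methods.
#' @param pca_grid Candidate PCA component counts.
#' @return Long-format data.frame with one row per ratio, arm, feature
#'   method and classifier: mean `accuracy` and mean `weighted_f1`.
#' @export
run_classification_experiment <- function(X, labels,
                                          ratios = seq(0.1, 0.9, by = 0.1),
                                          arms = c("observed", "recovered"),
                                          cfg = dsnn_config(),
                                          feature_methods = c("pca", "chi_square", "mutual_info"),
                                          classifiers = c("knn3", "linear_svm"),
                                          n_repeats = 20, n_folds = 5,
                                          feature_grid = c(10, 50, 100, 500, 1000),
                                          pca_grid = c(5, 10, 20, 50)) {
  vals <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(vals))
  if (length(unique(labels)) != 2) stop("labels must contain exactly two classes")
  if (any(table(labels) < n_folds))
    stop("every class needs at least ", n_folds, " samples to stratify ",
         n_folds, " folds")
  stopifnot(all(arms %in% c("observed", "recovered", "original")))

  out <- list(); i <- 0L
  for (r_idx in seq_along(ratios)) {
    ratio <- ratios[r_idx]
    mask_seed <- derive_seed(cfg$seed, 5000L + r_idx)
    mask <- random_mask(nrow(vals), ncol(vals), ratio, seed = mask_seed)
    arm_mats <- list(original = vals, observed = vals * mask)
    if ("recovered" %in% arms) {
      run_cfg <- cfg; run_cfg$seed <- mask_seed
      arm_mats$recovered <- dsnn_impute(vals * mask, mask, run_cfg)
    }
    for (arm in arms) {
      M <- arm_mats[[arm]]
      for (fm in feature_methods) for (clf in classifiers) {
        grid <- if (fm == "pca") pca_grid else feature_grid
        accs <- f1s <- numeric(0)
        for (rep_i in seq_len(n_repeats)) {
          fold_seed <- derive_seed(cfg$seed, 9000L + r_idx * 100L + rep_i)
          res <- with_local_seed(fold_seed, {
            folds <- stratified_folds(labels, n_folds)
            pred <- character(length(labels))
            for (f in seq_len(n_folds)) {
              tr <- folds != f
              k <- select_grid_value(M[tr, , drop = FALSE], labels[tr],
                                     fm, clf, grid)
              red <- reduce_features(M[tr, , drop = FALSE],
                                     M[!tr, , drop = FALSE], labels[tr],
                                     fm, k)
              pred[!tr] <- fit_predict(red$train, labels[tr], red$test, clf)
            }
            pred
          })
          accs <- c(accs, accuracy_score(labels, res))
          f1s <- c(f1s, weighted_f1(labels, res))
        }
        i <- i + 1L
        out[[i]] <- data.frame(sampling_ratio = ratio, matrix_arm = arm,
                               feature_method = fm, classifier = clf,
                               accuracy = mean(accs),
                               weighted_f1 = mean(f1s))
      }
    }
  }
  do.call(rbind, out)
}

#' Read a two-column sample label table
#'
#' @param path Delimited file with columns sample_id, class (no header by
#'   default).
#' @param sep Field separator.
#' @param header Whether a header row is present.
#' @return Named character vector of classes, names = sample ids.
#' @export
read_labels <- function(path, sep = "\t", header = FALSE) {
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character")
  stats::setNames(df[[2]], df[[1]])
}
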