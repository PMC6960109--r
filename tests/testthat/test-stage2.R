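test_that("zero_outliers applies the column band test", {
  # observed column [1,2,3]: mean 2, sample sd 1; band 0.2
  Y <- matrix(c(1, 2, 3), 3, 1)
  mask <- matrix(1, 3, 1)
  Xt <- matrix(c(2.1, 1.5, 2.05), 3, 1)
  zo <- zero_outliers(Xt, Y, mask, lambda2 = 0.2)
  expect_equal(c(zo$X_rec), c(2.1, 0, 2.05))
  expect_equal(c(zo$X_inv_rec), c(0, 1, 0))
  # infinite band keeps everything
  zoi <- zero_outliers(Xt, Y, mask, lambda2 = Inf)
  expect_equal(zoi$X_rec, Xt)
  expect_true(all(zoi$X_inv_rec == 0))
  # constant observed column (sd 0) is left untouched
  Yc <- matrix(2, 3, 1)
  zoc <- zero_outliers(Xt, Yc, mask, lambda2 = 0.2)
  expect_equal(zoc$X_rec, Xt)
  # a column with no observed entries is rejected
  expect_error(zero_outliers(Xt, Y, matrix(0, 3, 1), 0.2), "no observed|column")
})

test_that("zero_outliers scope='missing' never discards observed entries", {
  Y <- matrix(c(1, 2, 3, 0), 4, 1)
  mask <- matrix(c(1, 1, 1, 0), 4, 1)
  Xt <- matrix(c(1, 9, 3, 9), 4, 1)        # 9s are far outside the band
  zo_all <- zero_outliers(Xt, Y, mask, 0.2, scope = "all")
  zo_mis <- zero_outliers(Xt, Y, mask, 0.2, scope = "missing")
  expect_equal(c(zo_all$X_inv_rec), c(1, 1, 1, 1))   # everything strays
  expect_equal(c(zo_mis$X_inv_rec), c(0, 0, 0, 1))   # only the imputed entry
  expect_equal(zo_mis$X_rec[1:3, 1], Xt[1:3, 1])
})

test_that("init_estimate fills the zeroed support with seeded uniforms", {
  X_rec <- matrix(c(1, 0, 2, 0), 2, 2)
  ind <- (X_rec == 0) * 1
  a <- init_estimate(X_rec, ind, seed = 33)
  b <- init_estimate(X_rec, ind, seed = 33)
  expect_identical(a, b)                                  # determinism
  expect_true(all(a[ind == 1] >= 0 & a[ind == 1] < 1))    # U[0,1) range
  expect_equal(a[ind == 0], X_rec[ind == 0])
  expect_equal(init_estimate(X_rec, 0 * ind, seed = 1), X_rec)
})

test_that("svt soft-thresholds singular values", {
  set.seed(14)
  V <- matrix(stats::rnorm(30), 5, 6)
  expect_equal(svt(V, 0), V, tolerance = 1e-10)
  expect_equal(svt(V, max(svd(V)$d) + 1), matrix(0, 5, 6))
  expect_equal(svt(diag(c(3, 1)), 1), diag(c(2, 0)))
  # non-expansiveness on random pairs
  for (i in 1:25) {
    A <- matrix(stats::rnorm(20), 4, 5)
    B <- matrix(stats::rnorm(20), 4, 5)
    expect_lte(sqrt(sum((svt(A, 0.7) - svt(B, 0.7))^2)),
               sqrt(sum((A - B)^2)) + 1e-10)
  }
  # nuclear norm and rank never increase
  for (i in 1:10) {
    A <- matrix(stats::rnorm(24), 4, 6)
    s_in <- svd(A)$d; s_out <- svd(svt(A, 0.5))$d
    expect_lte(sum(s_out), sum(s_in) + 1e-10)
    expect_lte(sum(s_out > 1e-10), sum(s_in > 1e-10))
  }
})

test_that("split_bregman_denoise fixes retained entries and reaches fixed points", {
  set.seed(15)
  X_rec <- matrix(stats::runif(20, 1, 3), 4, 5)
  ind0 <- matrix(0, 4, 5)
  dn <- split_bregman_denoise(X_rec, ind0, denoise_config(seed = 2))
  expect_equal(dn$X_hat, X_rec)                 # fixed point, no free entries
  expect_equal(dn$iterations, 1L)
  # tau = 0 stops at an init-consistent fixed point within 2 iterations
  ind <- matrix(rbinom(20, 1, 0.3), 4, 5)
  X_rec2 <- X_rec * (1 - ind)
  dn0 <- split_bregman_denoise(X_rec2, ind, denoise_config(tau = 0, seed = 2))
  expect_lte(dn0$iterations, 2L)
  expect_equal(dn0$X_hat, init_estimate(X_rec2, ind, 2))
  # retained entries pass through unchanged, with either B-update
  for (bu in c("lagged", "direct")) {
    dnb <- split_bregman_denoise(X_rec2, ind,
                                 denoise_config(tau = 5, seed = 2,
                                                b_update = bu))
    expect_equal(dnb$X_hat[ind == 0], X_rec2[ind == 0])
  }
  # determinism
  d1 <- split_bregman_denoise(X_rec2, ind, denoise_config(seed = 7))
  d2 <- split_bregman_denoise(X_rec2, ind, denoise_config(seed = 7))
  expect_identical(d1$X_hat, d2$X_hat)
})

test_that("low-rank repaint beats the random initialisation on zeroed entries", {
  # rank-2 truth: constant baseline plus one strong factor
  set.seed(16)
  u <- stats::rnorm(40); v <- stats::rnorm(40)
  truth <- 5 + outer(u, v) * (150 / sqrt(sum(u^2) * sum(v^2)))
  ind <- matrix(rbinom(1600, 1, 0.2), 40, 40)
  X_rec <- truth * (1 - ind)
  init <- init_estimate(X_rec, ind, seed = 3)
  dn <- split_bregman_denoise(X_rec, ind, denoise_config(seed = 3))
  err_dn <- sqrt(sum((dn$X_hat[ind == 1] - truth[ind == 1])^2))
  err_init <- sqrt(sum((init[ind == 1] - truth[ind == 1])^2))
  expect_lt(err_dn, err_init)
})
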