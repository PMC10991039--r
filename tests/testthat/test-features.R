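test_that("eigen profiles match closed forms", {
  expect_equal(eigen_profile(diag(5)), rep(1, 5))
  expect_equal(eigen_profile(equicorr(2, 0.36)), c(1.36, 0.64))
  expect_equal(eigen_profile(equicorr(4, 0.5)), c(2.5, 0.5, 0.5, 0.5))
  expect_error(eigen_profile(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("eigenvalue sum and Frobenius identities hold on sample matrices", {
  x <- make_condition_data(k = 3, n = 300, vpf = 4, rho = 0.2, seed = 4)
  r <- correlation_matrix(x)
  lam <- eigen_profile(r)
  expect_equal(sum(lam), ncol(x), tolerance = 1e-8)
  expect_equal(sqrt(sum(lam^2)), norm(r, "F"), tolerance = 1e-10)
  expect_true(all(diff(lam) <= 1e-12))
})

test_that("correlation_matrix handles exact and degenerate cases", {
  x <- cbind(a = 1:10 + 0, b = 1:10 + 0, c = rnorm(10))
  expect_equal(correlation_matrix(x)[1, 2], 1.0)
  y <- cbind(a = rnorm(20), b = 0)
  y[, 2] <- -y[, 1]
  expect_equal(correlation_matrix(y)[1, 2], -1.0)
  expect_error(correlation_matrix(cbind(rnorm(10), rep(2, 10))),
               "zero variance")
})

test_that("Gini coefficient matches hand-computed values", {
  expect_equal(gini_coef(c(0.2, 0.2, 0.2)), 0)
  expect_equal(gini_coef(c(0, 1)), 0.5)
  # brute-force pairwise-difference oracle
  brute <- function(x) {
    s <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) s <- s + abs(x[i] - x[j])
    s / (2 * length(x)^2 * mean(x))
  }
  expect_equal(gini_coef(1:4), 0.25)
  expect_equal(brute(1:4), 0.25)
  set.seed(31)
  for (i in 1:10) {
    v <- runif(7)
    expect_equal(gini_coef(v), brute(v))
  }
  expect_error(gini_coef(c(0, 0, 0)), "all-zero")
})

test_that("Gini is scale invariant", {
  set.seed(17)
  for (i in 1:10) {
    v <- runif(9)
    expect_equal(gini_coef(v), gini_coef(v * runif(1, 0.1, 50)))
  }
})

test_that("Kolm index matches direct evaluation and responds to spreads", {
  expect_equal(kolm_index(rep(0.4, 6)), 0)
  expect_equal(kolm_index(c(0, 1)), log(cosh(0.5)), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:10) {
    v <- runif(8, 0, 1)
    d <- runif(1, 0.05, 0.3)
    spread <- v + d * sign(v - mean(v))  # mean-preserving spread
    expect_gt(kolm_index(spread), kolm_index(v))
  }
  # overflow guard: huge aversion-scaled gaps stay finite
  expect_true(is.finite(kolm_index(c(0, 1000), aversion = 5)))
})

test_that("feature vectors have a stable schema and documented invariances", {
  x <- make_condition_data(k = 3, n = 300, vpf = 4, rho = 0.2, seed = 6)
  f <- extract_features(x)
  expect_false(anyNA(f))
  expect_equal(length(f), length(extract_features(x * 1)))
  expect_equal(f[["n"]], 300)
  expect_equal(f[["p"]], 12)
  expect_equal(f[["p_over_n"]], 12 / 300)
  expect_gte(f[["gini_cor"]], 0); expect_lt(f[["gini_cor"]], 1)
  expect_equal(f[["det_r"]], det(correlation_matrix(x)))
  # row permutation invariance
  expect_equal(extract_features(x[sample(nrow(x)), ]), f)
  # column sign flips leave the |r|-based and spectral features unchanged
  x2 <- x
  x2[, c(2, 5)] <- -x2[, c(2, 5)]
  expect_equal(extract_features(x2), f, tolerance = 1e-10)
})

test_that("equicorrelation determinant closed form backs the det feature", {
  expect_equal(det(equicorr(4, 0.5)), (1 - 0.5)^3 * (1 + 3 * 0.5),
               tolerance = 1e-12)
})

test_that("near-identity data put about half the eigenvalues above 1", {
  m <- factor_model(matrix(1e-6, 10, 1))
  counts <- vapply(1:10, function(s) {
    x <- simulate_factor_data(m, 2000, seed = 40 + s)
    extract_features(x)[["n_eig_gt_1"]]
  }, numeric(1))
  expect_gt(mean(counts), 2.5)
  expect_lt(mean(counts), 7.5)
})
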