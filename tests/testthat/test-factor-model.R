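test_that("factor_model matches single-factor closed forms", {
  m <- factor_model(cbind(c(0.6, 0.5)))
  expect_equal(m$sigma[1, 2], 0.30)
  expect_equal(unname(m$uniquenesses), c(0.64, 0.75))
  expect_equal(diag(m$sigma), c(1, 1))
})

test_that("orthogonal simple structure yields an exactly block-diagonal sigma", {
  spec <- condition_spec(k = 3, n = 250, vpf = 4, rho = 0, cross = "zero")
  m <- build_population(spec, seed = 7)
  expect_equal(m$p, 12L)
  for (f1 in 1:2) for (f2 in (f1 + 1):3) {
    rows <- ((f1 - 1) * 4 + 1):(f1 * 4)
    cols <- ((f2 - 1) * 4 + 1):(f2 * 4)
    expect_true(all(m$sigma[rows, cols] == 0))
  }
})

test_that("hard bin combinations stay proper across many seeded draws", {
  spec <- condition_spec(k = 5, n = 500, vpf = 7, rho = 0.5,
                         primary = "large", cross = "medium")
  for (s in 1:200) {
    m <- build_population(spec, seed = s)
    expect_true(all(m$uniquenesses > 0 & m$uniquenesses < 1))
    expect_gt(min(eigen(m$sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_lt(max(abs(diag(m$sigma) - 1)), 1e-12)
  }
})

test_that("sampled loadings stay inside their bins", {
  spec <- condition_spec(k = 3, n = 500, vpf = 4, rho = 0.2,
                         primary = "small", cross = "medium")
  for (s in 1:25) {
    m <- build_population(spec, seed = s)
    for (f in 1:3) {
      rows <- ((f - 1) * 4 + 1):(f * 4)
      expect_true(all(m$loadings[rows, f] >= 0.35 & m$loadings[rows, f] <= 0.5))
      # exactly one cross-loading per variable, inside the medium bin
      cross <- m$loadings[rows, -f, drop = FALSE]
      expect_true(all(rowSums(cross != 0) == 1L))
      nz <- cross[cross != 0]
      expect_true(all(nz >= 0.1 & nz <= 0.2))
    }
  }
})

test_that("condition_spec rejects structurally invalid settings", {
  expect_error(condition_spec(k = 1, n = 100, vpf = 4, rho = 0.2), "rho")
  expect_error(condition_spec(k = 1, n = 100, vpf = 4, cross = "small"),
               "cross")
  expect_error(condition_spec(k = 3, n = 10, vpf = 4), "n >= p")
  expect_silent(condition_spec(k = 1, n = 100, vpf = 4))
})

test_that("simulated data have the right shape, scale and determinism", {
  spec <- condition_spec(k = 3, n = 250, vpf = 4, rho = 0.2)
  m <- build_population(spec, seed = 3)
  x <- simulate_factor_data(m, 250, seed = 9)
  expect_equal(dim(x), c(250L, 12L))
  expect_true(all(abs(apply(x, 2, var) - 1) < 0.35))
  expect_identical(x, simulate_factor_data(m, 250, seed = 9))
  expect_error(simulate_factor_data(m, 10), "n >= p")
})

test_that("large-sample correlations converge to the population value", {
  m <- factor_model(cbind(c(0.8, 0.8, 0.8)))
  x <- simulate_factor_data(m, 100000, seed = 11)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.64), 0.01)
})

test_that("independent-population data show near-zero correlations", {
  # identity covariance: mean absolute off-diagonal should be tiny at n=500
  m <- factor_model(matrix(1e-6, 5, 1))
  for (s in 1:20) {
    x <- simulate_factor_data(m, 500, seed = s)
    r <- correlation_matrix(x)
    expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
  }
})

test_that("design grid counts follow the crossed design with k = 1 pruning", {
  expect_equal(nrow(design_grid()), 342L)
  expect_equal(nrow(design_grid(factors = c(3, 5))), 324L)
  expect_equal(nrow(design_grid(factors = 1)), 18L)
  expect_equal(nrow(design_grid(1, 250, 4, 0, "medium", "zero")), 1L)
  expect_error(design_grid(factors = integer(0)))
  # deterministic ordering
  expect_identical(design_grid(), design_grid())
})
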