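test_that("run_study produces one record per condition x rep x method", {
  grid <- design_grid(1, 250, 4, 0, "large", "zero")
  rec <- run_study(grid, replications = 3,
                   methods = list(ekc = list(method = "ekc"),
                                  ekc2 = list(method = "ekc")),
                   seed = 5)
  expect_equal(nrow(rec), 6L)
  expect_setequal(unique(rec$method), c("ekc", "ekc2"))
  expect_true(all(rec$k_true == 1L))
  # paired design: both methods see the same data, so estimates coincide
  wide <- split(rec$k_hat, rec$method)
  expect_identical(wide$ekc, wide$ekc2)
})

test_that("aggregation arithmetic matches hand checks and identities", {
  rec <- data.frame(method = "m", k_true = 3,
                    k_hat = c(3, 3, 4), condition = 1, replication = 1:3)
  agg <- aggregate_study(rec)
  expect_equal(agg$accuracy, 2 / 3)
  expect_equal(agg$bias, 1 / 3)
  expect_equal(agg$overfactor_rate, 1 / 3)
  expect_equal(agg$underfactor_rate, 0)
  expect_equal(agg$accuracy + agg$underfactor_rate + agg$overfactor_rate, 1)
  expect_equal(agg$n_cells, 3L)
  expect_error(aggregate_study(rec, by = "nope"), "unknown grouping")
  # idempotence: re-aggregating the same records gives the same table
  expect_identical(aggregate_study(rec), aggregate_study(rec))
})

test_that("an oracle method scores perfect accuracy and zero bias everywhere", {
  set.seed(9)
  rec <- expand.grid(condition = 1:5, replication = 1:10, method = "oracle")
  rec$k_true <- sample(1:5, nrow(rec), replace = TRUE)
  rec$k_hat <- rec$k_true
  for (by in list("method", c("method", "condition"))) {
    agg <- aggregate_study(rec, by = by)
    expect_true(all(agg$accuracy == 1))
    expect_true(all(agg$bias == 0))
  }
})

test_that("agreement analysis handles the identical and disjoint extremes", {
  base <- expand.grid(condition = 1:4, replication = 1:5)
  base$k_true <- 3
  a <- cbind(base, method = "a", k_hat = rep(c(3, 4), 10))
  b <- cbind(base, method = "b", k_hat = rep(c(3, 4), 10))
  rec <- rbind(a, b)
  ag <- agreement_analysis(rec, "a", "b")
  expect_equal(ag$agreement_rate, 1)
  expect_equal(ag$accuracy_given_agreement, 0.5)
  expect_equal(ag$n_pairs, 20L)
  b2 <- b; b2$k_hat <- b2$k_hat + 1
  ag2 <- agreement_analysis(rbind(a, b2), "a", "b")
  expect_equal(ag2$agreement_rate, 0)
  expect_true(is.nan(ag2$accuracy_given_agreement))
  expect_error(agreement_analysis(rec, "a", "missing"), "no records")
})

test_that("journaled runs resume instead of recomputing", {
  grid <- design_grid(1, 250, 4, 0, "large", "zero")
  journal <- tempfile(fileext = ".jsonl")
  rec1 <- run_study(grid, replications = 2,
                    methods = list(ekc = list(method = "ekc")),
                    seed = 11, journal = journal)
  expect_equal(length(readLines(journal)), 2L)
  rec2 <- run_study(grid, replications = 2,
                    methods = list(ekc = list(method = "ekc")),
                    seed = 11, journal = journal)
  expect_null(rec2)  # nothing left to do
  unlink(journal)
})

test_that("a small paired smoke study completes with sane accuracy", {
  grid <- design_grid(c(1, 3), c(300), 4, 0, "large", "zero")
  rec <- run_study(grid, replications = 3,
                   methods = list(
                     cd = list(method = "cd", alpha = 0.05, n_rep = 40,
                               n_population = 1500),
                     ekc = list(method = "ekc")),
                   seed = 21)
  expect_equal(nrow(rec), 12L)
  expect_true(all(is.na(rec$error)))
  agg <- aggregate_study(rec)
  expect_true(all(agg$accuracy >= 0.25 & agg$accuracy <= 1))
  ag <- agreement_analysis(rec, "cd", "ekc")
  expect_gte(ag$agreement_rate, 0)
  expect_equal(ag$n_pairs, 6L)
})
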