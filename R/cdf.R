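# Comparison data forest (CDF): a random-forest classifier trained on
# features of comparison data sets generated under 1..k_max factor solutions
# predicts the number of factors for the empirical data set.

#' Build the labeled CDF training table
#'
#' For every candidate factor count f = 1..`k_max`, a comparison population
#' is generated for the empirical data, `n_rep` samples of the empirical
#' sample size are drawn, and [extract_features()] is applied to each. The
#' result is an exactly class-balanced table of `n_rep * k_max` rows whose
#' `label` column is the generating factor count.
#'
#' @param data Empirical data matrix.
#' @param k_max Largest candidate number of factors.
#' @param n_rep Comparison data sets per factor solution.
#' @param n_population Comparison population size.
#' @param seed Optional integer master seed.
#' @param max_iterations,max_stalled Generator controls, passed to
#'   [gen_comparison_population()].
#' @return Data frame of features plus a `label` factor with levels
#'   `1..k_max`.
#' @export
build_training_table <- function(data, k_max = 8L, n_rep = 1000L,
                                 n_population = 10000L, seed = NULL,
                                 max_iterations = 300L, max_stalled = 5L) {
  data <- check_data_matrix(data)
  k_max <- min(as.integer(k_max), ncol(data) - 2L)
  n <- nrow(data)
  rows <- lapply(seq_len(k_max), function(f) {
    pop <- gen_comparison_population(data, f, n_population = n_population,
                                     max_iterations = max_iterations,
                                     max_stalled = max_stalled,
                                     seed = substream(seed, 100L + f))
    samples <- draw_comparison_samples(pop, n = n, n_rep = n_rep,
                                       seed = substream(seed, 200L + f))
    t(vapply(samples, extract_features,
             numeric(length(extract_features(samples[[1L]])))))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$label <- factor(rep(seq_len(k_max), each = n_rep),
                      levels = seq_len(k_max))
  tab
}

#' Train the comparison-data random forest
#'
#' A classification forest of `n_trees` trees (default 500) with
#' `floor(sqrt(#features))` candidate split variables per node, grown on the
#' labeled feature table via the ranger implementation. Deterministic given
#' `seed` (single-threaded).
#'
#' @param table Labeled feature table from [build_training_table()].
#' @param n_trees Number of trees (default 500).
#' @param seed Optional integer seed.
#' @return A `ranger` classification forest (out-of-bag accuracy available as
#'   `1 - prediction.error`).
#' @export
train_forest <- function(table, n_trees = 500L, seed = NULL) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (nlevels(droplevels(table$label)) < 2L) {
    stop("training table needs at least 2 distinct labels", call. = FALSE)
  }
  n_feat <- ncol(table) - 1L
  ranger::ranger(
    dependent.variable.name = "label", data = table,
    num.trees = n_trees, mtry = floor(sqrt(n_feat)),
    num.threads = 1L,
    seed = if (is.null(seed)) stats::runif(1L, 1, 2^31 - 2) else seed
  )
}

#' Comparison data forest estimate of the number of factors
#'
#' Trains a forest on comparison data features ([build_training_table()],
#' [train_forest()]) and predicts the label of the empirical data set's own
#' feature vector. The per-class tree-vote proportions are returned; ties in
#' the vote maximum resolve to the smallest candidate count.
#'
#' @inheritParams build_training_table
#' @param n_trees Number of trees in the forest (default 500).
#' @return List with `k_hat`, `votes` (length `k_max`, sums to 1),
#'   `oob_accuracy`, `training_size`.
#' @export
run_cdf <- function(data, k_max = 8L, n_rep = 1000L, n_population = 10000L,
                    n_trees = 500L, seed = NULL, max_iterations = 300L,
                    max_stalled = 5L) {
  data <- check_data_matrix(data)
  tab <- build_training_table(data, k_max = k_max, n_rep = n_rep,
                              n_population = n_population, seed = seed,
                              max_iterations = max_iterations,
                              max_stalled = max_stalled)
  rf <- train_forest(tab, n_trees = n_trees, seed = substream(seed, 300L))
  emp <- as.data.frame(t(extract_features(data)))
  pred <- stats::predict(rf, data = emp, predict.all = TRUE,
                         num.threads = 1L)
  tree_votes <- as.integer(pred$predictions)  # class indices 1..k_max
  votes <- tabulate(tree_votes, nbins = k_max) / length(tree_votes)
  k_hat <- which.max(votes)  # which.max takes the first (smallest) maximum
  list(k_hat = as.integer(k_hat), votes = votes,
       oob_accuracy = 1 - rf$prediction.error,
       training_size = nrow(tab))
}
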