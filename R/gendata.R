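# Comparison-data generator: iteratively builds a finite population whose
# correlation matrix reproduces an empirical one under a k-factor structure
# while each column's marginal distribution is a bootstrap copy of the
# corresponding empirical column.

# Unrotated orthogonal k-factor loadings by iterated principal axis: the
# correlation matrix diagonal is replaced by communalities and re-decomposed
# until the communalities stabilize. Unlike a raw principal-component
# truncation, this targets the off-diagonal structure, so fit improves with
# k instead of chasing the unit diagonal.
principal_axis_loadings <- function(r, k, max_iter = 50L, tol = 1e-3) {
  p <- ncol(r)
  h2_old <- rep(99, p)
  rr <- r
  L <- NULL
  for (i in seq_len(max_iter)) {
    eg <- eigen(rr, symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(k)], 0)
    L <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    h2 <- rowSums(L^2)
    if (max(abs(h2 - h2_old)) < tol) break
    h2_old <- h2
    diag(rr) <- h2
  }
  L
}

#' Generate a k-factor comparison population for an empirical data set
#'
#' Iterative generator in the GenData tradition. Each empirical column is
#' first bootstrapped to `n_population` values; these fixed marginals are the
#' only values the population will ever contain. An intermediate correlation
#' matrix, initialized at the empirical correlation matrix, is then refined:
#' at every iteration an unrotated orthogonal k-factor loading pattern is
#' extracted from the intermediate matrix (iterated principal axis), scores are
#' generated as common-part plus unique-part normal draws, the bootstrap
#' marginals are imposed by rank substitution, and the residual between the
#' empirical and reproduced correlation matrices (its RMSR over the unique
#' off-diagonal entries) drives a feedback update of the intermediate matrix.
#' Improvements are kept (best-so-far) and reset the feedback step to
#' `initial_step`; each non-improvement restores the best state and halves
#' the step relative to the current run of stalls. The search stops after
#' `max_stalled` consecutive non-improvements or `max_iterations` iterations.
#'
#' @param data Empirical data matrix (n x p).
#' @param k Number of factors for the comparison population (1 <= k < p).
#' @param n_population Population size (default 10000).
#' @param max_iterations Iteration cap.
#' @param max_stalled Consecutive non-improvements tolerated before stopping.
#' @param initial_step Initial feedback step size on the residual matrix.
#' @param seed Optional integer seed.
#' @return Object of class `"comparison_population"`: `values`
#'   (`n_population` x p), `marginals` (sorted bootstrap values per column),
#'   `target_k`, `achieved_rmsr`, `iterations_used`, `pd_repairs`.
#' @export
gen_comparison_population <- function(data, k, n_population = 10000L,
                                      max_iterations = 300L, max_stalled = 5L,
                                      initial_step = 1, seed = NULL) {
  data <- check_data_matrix(data)
  p <- ncol(data)
  k <- as.integer(k)
  if (k < 1L || k >= p) stop("need 1 <= k < p", call. = FALSE)
  if (p < k + 2L) stop("need at least k + 2 variables", call. = FALSE)
  r_emp <- correlation_matrix(data)
  if (!all(is.finite(r_emp))) stop("non-finite empirical correlations", call. = FALSE)
  off <- upper.tri(r_emp)

  with_seed(seed, {
    marginals <- apply(data, 2L, function(col)
      sort(sample(col, n_population, replace = TRUE)))

    # the underlying factor and unique scores are drawn once: the search over
    # intermediate correlation matrices then has a deterministic objective,
    # so best-so-far bookkeeping tracks real improvements, not sampling noise
    shared_base <- matrix(stats::rnorm(n_population * k), n_population, k)
    unique_base <- matrix(stats::rnorm(n_population * p), n_population, p)

    r_int <- r_emp
    best <- list(rmsr = Inf, values = NULL, r_int = r_int, delta = NULL)
    step <- initial_step
    stalled <- 0L
    iters <- 0L
    repairs <- 0L

    for (it in seq_len(max_iterations)) {
      iters <- it
      L <- principal_axis_loadings(r_int, k)
      uvar <- pmax(1 - rowSums(L^2), 0)
      scores <- shared_base %*% t(L) +
        unique_base %*% diag(sqrt(uvar), p)
      # rank substitution: sorted bootstrap values replace generated values
      # in rank order, preserving each column's marginal exactly
      values <- scores
      for (j in seq_len(p)) {
        values[order(scores[, j]), j] <- marginals[, j]
      }
      r_rep <- stats::cor(values)
      delta <- r_emp - r_rep
      rmsr <- sqrt(mean(delta[off]^2))

      if (rmsr < best$rmsr) {
        best <- list(rmsr = rmsr, values = values, r_int = r_int, delta = delta)
        stalled <- 0L
        step <- initial_step
        r_int <- r_int + step * delta
      } else {
        stalled <- stalled + 1L
        if (stalled >= max_stalled) break
        # step shrinks with the current run of non-improvements and resets
        # to initial_step as soon as an improvement is found again
        step <- initial_step * 0.5^stalled
        r_int <- best$r_int + step * best$delta
      }
      # keep the intermediate matrix a proper correlation matrix
      diag(r_int) <- 1
      ev <- eigen(r_int, symmetric = TRUE)
      if (min(ev$values) < -1e-8) {
        repairs <- repairs + 1L
        lam2 <- pmax(ev$values, 0)
        r_int <- ev$vectors %*% diag(lam2, p) %*% t(ev$vectors)
        d <- sqrt(pmax(diag(r_int), .Machine$double.eps))
        r_int <- r_int / tcrossprod(d)
        diag(r_int) <- 1
      }
    }
    if (repairs > 0L) {
      message(sprintf("intermediate correlation matrix repaired %d time(s) (eigenvalue clipping)",
                      repairs))
    }
    colnames(best$values) <- colnames(data)
    structure(list(values = best$values, marginals = marginals,
                   target_k = k, achieved_rmsr = best$rmsr,
                   iterations_used = iters, pd_repairs = repairs),
              class = "comparison_population")
  })
}

#' Draw replicate samples from a comparison population
#'
#' Each of the `n_rep` samples is a simple random sample of `n` rows drawn
#' without replacement within itself; samples are independent of one another
#' (rows may recur across samples). A drawn sample with a constant column is
#' redrawn a bounded number of times before erroring.
#'
#' @param pop A [gen_comparison_population()] result.
#' @param n Rows per sample (the empirical sample size); `n <= n_population`.
#' @param n_rep Number of samples.
#' @param seed Optional integer seed.
#' @return List of `n_rep` matrices, each `n` x p.
#' @export
draw_comparison_samples <- function(pop, n, n_rep, seed = NULL) {
  stopifnot(inherits(pop, "comparison_population"))
  n <- as.integer(n); n_rep <- as.integer(n_rep)
  n_population <- nrow(pop$values)
  if (n > n_population) stop("n exceeds the population size", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_rep), function(i) {
      for (try in 1:10) {
        idx <- sample.int(n_population, n)
        smp <- pop$values[idx, , drop = FALSE]
        if (all(apply(smp, 2L, stats::var) > 0)) return(smp)
      }
      stop("comparison samples degenerate: a column has zero variance",
           call. = FALSE)
    })
  })
}
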