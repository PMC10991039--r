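# Classical comparison data (CD) criterion: sequential comparison of
# eigenvalue RMSR distributions with a one-tailed Mann-Whitney U stopping
# rule.

#' Root mean squared residual between two eigenvalue profiles
#'
#' Residuals are element-wise differences between an empirical eigenvalue and
#' the corresponding comparison-data eigenvalue:
#' \eqn{\mathrm{RMSR} = \sqrt{\mathrm{mean}_j(\lambda_j - \lambda^{ref}_j)^2}}.
#'
#' @param empirical,comparison Equal-length eigenvalue profiles.
#' @return Non-negative scalar.
#' @export
rmsr_eigen <- function(empirical, comparison) {
  if (length(empirical) != length(comparison)) {
    stop("eigenvalue profiles must have equal length", call. = FALSE)
  }
  sqrt(mean((empirical - comparison)^2))
}

#' One-tailed Mann-Whitney U p-value for "b stochastically smaller than a"
#'
#' Wraps [stats::wilcox.test()] with `alternative = "greater"` on `(a, b)`:
#' exact enumeration for small tie-free samples (combined size <= 12), normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return p-value.
#' @export
u_test_less <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  exact <- (length(a) + length(b) <= 12L) && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value
  )
}

# Distributions of eigenvalue RMSR values for factor solutions f = 1..k.
# Returns a list of length k of numeric vectors (n_rep each). Sub-seeds are
# derived per factor solution so profiles are extendable without replay.
cd_rmsr_profile <- function(data, k, n_rep, n_population, seed = NULL,
                            max_iterations = 300L, max_stalled = 5L) {
  data <- check_data_matrix(data)
  emp <- eigen_profile(correlation_matrix(data))
  n <- nrow(data)
  lapply(seq_len(k), function(f) {
    pop <- gen_comparison_population(data, f, n_population = n_population,
                                     max_iterations = max_iterations,
                                     max_stalled = max_stalled,
                                     seed = substream(seed, 100L + f))
    samples <- draw_comparison_samples(pop, n = n, n_rep = n_rep,
                                       seed = substream(seed, 200L + f))
    vapply(samples, function(s)
      rmsr_eigen(emp, eigen_profile(correlation_matrix(s))), numeric(1L))
  })
}

# Apply the sequential stopping rule to precomputed RMSR distributions.
cd_decide <- function(rmsr_list, alpha) {
  k_avail <- length(rmsr_list)
  p_values <- numeric(0)
  for (f in seq_len(k_avail - 1L)) {
    pv <- u_test_less(rmsr_list[[f]], rmsr_list[[f + 1L]])
    p_values <- c(p_values, pv)
    if (pv >= alpha) {
      return(list(k_hat = f, p_values = p_values, censored = FALSE))
    }
  }
  list(k_hat = k_avail, p_values = p_values, censored = TRUE)
}

#' Comparison data estimate of the number of factors
#'
#' For f = 1, 2, ... a comparison population with f factors is generated,
#' `n_rep` samples of the empirical sample size are drawn from it, and each
#' sample's eigenvalue profile is scored by RMSR against the empirical
#' profile. The candidate count advances while the f-solution RMSR values
#' are significantly higher than those of the (f+1)-solution (one-tailed
#' Mann-Whitney U at level `alpha`); the first non-significant step returns
#' `k_hat = f`. Reaching `k_max` without a non-significant step returns
#' `k_max` with `censored = TRUE`.
#'
#' One population is generated per factor solution; sampling variability
#' enters only through the replicate draws.
#'
#' @param data Empirical data matrix.
#' @param alpha Significance level of the internal U test (default 0.05).
#' @param n_rep Comparison data sets per factor solution (default 1000).
#' @param n_population Comparison population size (default 10000).
#' @param k_max Largest candidate number of factors (default 8).
#' @param seed Optional integer master seed.
#' @param max_iterations,max_stalled Generator iteration controls, passed to
#'   [gen_comparison_population()].
#' @return List with `k_hat`, `p_values`, `rmsr_distributions` (per tested
#'   solution), `censored`.
#' @export
run_cd <- function(data, alpha = 0.05, n_rep = 1000L, n_population = 10000L,
                   k_max = 8L, seed = NULL, max_iterations = 300L,
                   max_stalled = 5L) {
  stopifnot(alpha > 0, alpha < 0.5)
  data <- check_data_matrix(data)
  k_max <- min(as.integer(k_max), ncol(data) - 2L)
  emp <- eigen_profile(correlation_matrix(data))
  n <- nrow(data)
  rmsr_one <- function(f) {
    pop <- gen_comparison_population(data, f, n_population = n_population,
                                     max_iterations = max_iterations,
                                     max_stalled = max_stalled,
                                     seed = substream(seed, 100L + f))
    samples <- draw_comparison_samples(pop, n = n, n_rep = n_rep,
                                       seed = substream(seed, 200L + f))
    vapply(samples, function(s)
      rmsr_eigen(emp, eigen_profile(correlation_matrix(s))), numeric(1L))
  }
  rmsr_list <- list(rmsr_one(1L))
  p_values <- numeric(0)
  k_hat <- k_max
  censored <- TRUE
  f <- 1L
  while (f < k_max) {
    rmsr_list[[f + 1L]] <- rmsr_one(f + 1L)
    pv <- u_test_less(rmsr_list[[f]], rmsr_list[[f + 1L]])
    p_values <- c(p_values, pv)
    if (pv >= alpha) {
      k_hat <- f
      censored <- FALSE
      break
    }
    f <- f + 1L
  }
  list(k_hat = k_hat, p_values = p_values, rmsr_distributions = rmsr_list,
       censored = censored)
}
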