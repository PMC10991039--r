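# Eigenvalue profiles and the data-characteristic feature set used by the
# comparison data forest (and, as diagnostics, by the other criteria).

#' Descending eigenvalue profile of a correlation matrix
#'
#' Full-matrix (principal-component) eigenvalues; no communality reduction.
#' For a p x p correlation matrix the eigenvalues sum to p, and the j-th one
#' equals the variance explained by the j-th principal component.
#'
#' @param r Symmetric correlation matrix with unit diagonal.
#' @return Numeric vector of length p, non-increasing.
#' @export
eigen_profile <- function(r) {
  r <- as.matrix(r)
  if (max(abs(r - t(r))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  eigen(r, symmetric = TRUE, only.values = TRUE)$values
}

#' Gini coefficient of a non-negative vector
#'
#' Mean absolute difference between all pairs, scaled by twice the mean:
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 m^2 \bar x)} for `m` values.
#' 0 for constant input; undefined (error) when all values are zero.
#'
#' @param x Non-negative numeric vector, length >= 2.
#' @return Gini coefficient in \[0, 1).
#' @export
gini_coef <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2L, all(is.finite(x)), all(x >= 0))
  m <- mean(x)
  if (m == 0) stop("Gini coefficient undefined for an all-zero vector", call. = FALSE)
  sum(abs(outer(x, x, "-"))) / (2 * length(x)^2 * m)
}

#' Kolm inequality index
#'
#' \eqn{K = (1/a) \log(\mathrm{mean}(\exp(a(\bar x - x_i))))} with aversion
#' parameter `a > 0`; 0 for constant input. Computed with a max-shift to
#' avoid overflow.
#'
#' @param x Numeric vector.
#' @param aversion Inequality-aversion parameter (default 1).
#' @return Non-negative Kolm index.
#' @export
kolm_index <- function(x, aversion = 1) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1L, all(is.finite(x)), aversion > 0)
  d <- aversion * (mean(x) - x)
  mx <- max(d)
  (log(mean(exp(d - mx))) + mx) / aversion
}

#' Extract the data-characteristic feature vector for one data set
#'
#' The fixed-order feature set the comparison data forest trains on: sample
#' size, number of variables, their ratio, the full eigenvalue profile,
#' cumulative explained-variance proportions for the first `min(p, 10)`
#' components, eigenvalue counts above 1 and 0.7, the determinant and four
#' matrix norms of the correlation matrix, and summaries of the absolute
#' off-diagonal correlations (mean, SD, Gini, Kolm, proportion >= 0.3).
#' The same function is applied to comparison samples and to the empirical
#' data set.
#'
#' @param data Numeric data matrix (n x p).
#' @return Named numeric vector; length and order depend only on p.
#' @export
extract_features <- function(data) {
  data <- check_data_matrix(data)
  n <- nrow(data); p <- ncol(data)
  r <- correlation_matrix(data)
  lam <- eigen_profile(r)
  n_cum <- min(p, 10L)
  cumvar <- cumsum(lam)[seq_len(n_cum)] / p
  abs_off <- abs(r[upper.tri(r)])
  out <- c(
    n = n, p = p, p_over_n = p / n,
    stats::setNames(lam, paste0("eig", seq_len(p))),
    stats::setNames(cumvar, paste0("cumvar", seq_len(n_cum))),
    n_eig_gt_1 = sum(lam > 1),
    n_eig_gt_07 = sum(lam > 0.7),
    det_r = det(r),
    norm_frobenius = norm(r, "F"),
    norm_colsum = norm(r, "O"),
    norm_maxentry = norm(r, "M"),
    norm_spectral = lam[1L],
    avg_abs_cor = mean(abs_off),
    sd_abs_cor = stats::sd(abs_off),
    gini_cor = gini_coef(abs_off),
    kolm_cor = kolm_index(abs_off),
    prop_large_cor = mean(abs_off >= 0.3)
  )
  out
}
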