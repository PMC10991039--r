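# Empirical Kaiser criterion: sample eigenvalues compared sequentially to
# sample-size-adjusted reference eigenvalues.

#' Empirical Kaiser criterion reference eigenvalues
#'
#' \deqn{\ell^{ref}_j = \max\!\left(\frac{p - \sum_{i<j} \lambda_i}{p - j + 1}
#'   \left(1 + \sqrt{p/n}\right)^2,\; 1\right)}
#' The first reference depends only on (p, n); later references shrink the
#' asymptotic upper edge by the variance already absorbed by preceding
#' eigenvalues, and no reference ever falls below the Kaiser threshold of 1.
#'
#' @param eigs Descending eigenvalue profile of the sample correlation
#'   matrix.
#' @param n Sample size; the reference formula assumes `n > p`.
#' @return Numeric vector of reference values, all >= 1.
#' @export
ekc_references <- function(eigs, n) {
  p <- length(eigs)
  stopifnot(p >= 2L)
  if (n <= p) warning("EKC references assume n > p", call. = FALSE)
  edge <- (1 + sqrt(p / n))^2
  prior <- c(0, cumsum(eigs)[-p])
  pmax((p - prior) / (p - seq_len(p) + 1) * edge, 1)
}

#' Empirical Kaiser criterion estimate of the number of factors
#'
#' Sequential rule: `k_raw` is the largest j such that every eigenvalue up to
#' the j-th exceeds its reference (the scan stops at the first failure, so
#' non-contiguous exceedances never count). `k_raw = 0` is possible when the
#' first eigenvalue already fails; `k_hat` floors it at 1, since a retention
#' criterion must propose at least one factor, and the raw value is kept for
#' diagnostics.
#'
#' @param data Empirical data matrix.
#' @return List with `k_hat` (>= 1), `k_raw` (>= 0), `references`,
#'   `eigenvalues`.
#' @export
run_ekc <- function(data) {
  data <- check_data_matrix(data)
  eigs <- eigen_profile(correlation_matrix(data))
  refs <- ekc_references(eigs, nrow(data))
  exceeds <- eigs > refs
  k_raw <- if (!exceeds[1L]) 0L else {
    fails <- which(!exceeds)
    if (length(fails) == 0L) length(eigs) else fails[1L] - 1L
  }
  list(k_hat = max(1L, k_raw), k_raw = as.integer(k_raw),
       references = refs, eigenvalues = eigs)
}
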