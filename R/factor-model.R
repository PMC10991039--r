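# Population factor models and the multivariate-normal data-generating process
# used throughout the evaluation study.

.loading_bins <- list(
  primary = list(small = c(0.35, 0.50), medium = c(0.50, 0.65),
                 large = c(0.65, 0.80)),
  cross   = list(zero = c(0, 0), small = c(0, 0.10), medium = c(0.10, 0.20))
)

resolve_bin <- function(x, which = c("primary", "cross")) {
  which <- match.arg(which)
  if (is.character(x)) {
    bins <- .loading_bins[[which]]
    if (!x %in% names(bins)) {
      stop(sprintf("unknown %s loading bin '%s'", which, x), call. = FALSE)
    }
    bins[[x]]
  } else {
    x <- as.numeric(x)
    stopifnot(length(x) == 2L, x[1] <= x[2])
    x
  }
}

#' Construct a population factor model from explicit parameters
#'
#' Builds the implied population correlation structure
#' \eqn{\Sigma = L \Phi L^\top + \Psi} for standardized variables, where
#' uniquenesses are defined residually as
#' \eqn{\psi_i = 1 - (L \Phi L^\top)_{ii}} so that \eqn{\Sigma} has unit
#' diagonal.
#'
#' @param loadings p x k matrix of standardized loadings.
#' @param phi k x k factor correlation matrix (identity if omitted).
#' @return Object of class `"factor_model"` with elements `loadings`, `phi`,
#'   `uniquenesses`, `sigma`, `k`, `p`.
#' @examples
#' m <- factor_model(cbind(c(0.6, 0.5)))
#' m$sigma[1, 2]        # 0.30
#' m$uniquenesses       # 0.64 0.75
#' @export
factor_model <- function(loadings, phi = NULL) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  p <- nrow(loadings)
  if (is.null(phi)) phi <- diag(k)
  phi <- as.matrix(phi)
  stopifnot(nrow(phi) == k, ncol(phi) == k)
  if (max(abs(phi - t(phi))) > 1e-12 || any(abs(diag(phi) - 1) > 1e-12)) {
    stop("phi must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("phi must be positive semi-definite", call. = FALSE)
  }
  common <- loadings %*% phi %*% t(loadings)
  uniq <- 1 - diag(common)
  if (any(uniq <= 0) || any(uniq >= 1)) {
    stop("uniquenesses must lie strictly in (0, 1); loadings too large",
         call. = FALSE)
  }
  sigma <- common
  diag(sigma) <- 1
  sigma <- (sigma + t(sigma)) / 2
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("implied correlation matrix is not positive definite", call. = FALSE)
  }
  structure(list(loadings = loadings, phi = phi, uniquenesses = uniq,
                 sigma = sigma, k = k, p = p),
            class = "factor_model")
}

#' Specify one simulation condition
#'
#' A condition fixes the true number of factors `k`, the sample size `n`, the
#' number of indicator variables per factor `vpf`, the inter-factor
#' correlation `rho`, and the primary/cross loading magnitude bins. For
#' single-factor conditions `rho` and cross-loadings are structurally
#' inapplicable and must be 0 / `"zero"`.
#'
#' @param k True number of factors (>= 1).
#' @param n Sample size (must exceed `k * vpf`).
#' @param vpf Indicator variables per factor.
#' @param rho Correlation between every pair of factors.
#' @param primary Primary-loading bin: `"small"` (\[0.35, 0.5\]),
#'   `"medium"` (\[0.5, 0.65\]), `"large"` (\[0.65, 0.8\]), or a numeric range.
#' @param cross Cross-loading bin: `"zero"`, `"small"` (\[0, 0.1\]),
#'   `"medium"` (\[0.1, 0.2\]), or a numeric range.
#' @return Object of class `"condition_spec"`.
#' @export
condition_spec <- function(k, n, vpf, rho = 0, primary = "medium",
                           cross = "zero") {
  k <- as.integer(k); n <- as.integer(n); vpf <- as.integer(vpf)
  stopifnot(k >= 1L, vpf >= 2L, rho >= -1, rho <= 1)
  if (n < k * vpf + 1L) stop("need n >= p + 1", call. = FALSE)
  if (k == 1L) {
    if (rho != 0) stop("rho is inapplicable when k = 1", call. = FALSE)
    cross_rng <- resolve_bin(cross, "cross")
    if (any(cross_rng != 0)) {
      stop("cross-loadings are inapplicable when k = 1", call. = FALSE)
    }
    cross <- "zero"
  }
  structure(list(k = k, n = n, vpf = vpf, rho = rho,
                 primary = primary, cross = cross),
            class = "condition_spec")
}

#' Draw a population factor model for a simulation condition
#'
#' Each variable gets exactly one primary loading, drawn uniformly from the
#' condition's primary bin, on its assigned factor (`vpf` variables per
#' factor), and one cross-loading, drawn uniformly from the cross bin, on a
#' randomly chosen non-primary factor (the `"zero"` bin yields exact zeros).
#' One cross-loading per variable keeps every grid cell proper: loading all
#' non-primary factors simultaneously drives communalities above 1 in the
#' large-loading, high-correlation cells. All off-diagonal
#' entries of the factor correlation matrix equal `rho`. Draws whose implied
#' model is improper (any uniqueness <= 0.05 or a non-positive-definite
#' correlation matrix) are rejected and redrawn, up to `max_tries` times.
#'
#' @param spec A [condition_spec()].
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @param max_tries Rejection-sampling budget for improper draws.
#' @return A [factor_model()].
#' @export
build_population <- function(spec, seed = NULL, max_tries = 100L) {
  stopifnot(inherits(spec, "condition_spec"))
  prim <- resolve_bin(spec$primary, "primary")
  crss <- resolve_bin(spec$cross, "cross")
  k <- spec$k; vpf <- spec$vpf; p <- k * vpf
  phi <- matrix(spec$rho, k, k); diag(phi) <- 1
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      L <- matrix(0, p, k)
      for (f in seq_len(k)) {
        rows <- ((f - 1L) * vpf + 1L):(f * vpf)
        L[rows, f] <- stats::runif(vpf, prim[1], prim[2])
        if (k > 1L && crss[2] > 0) {
          for (i in rows) {
            target <- sample(setdiff(seq_len(k), f), 1L)
            L[i, target] <- stats::runif(1L, crss[1], crss[2])
          }
        }
      }
      m <- tryCatch(factor_model(L, phi), error = function(e) NULL)
      if (!is.null(m) && all(m$uniquenesses > 0.05)) return(m)
    }
    stop(sprintf(
      "no proper model found in %d tries (bin combination may be infeasible)",
      max_tries), call. = FALSE)
  })
}

#' Simulate multivariate normal data from a population model
#'
#' Rows are i.i.d. draws from \eqn{N_p(0, \Sigma)} with \eqn{\Sigma} the
#' model's implied correlation matrix, so population variances are 1 and the
#' covariance and correlation structures coincide.
#'
#' @param model A [factor_model()].
#' @param n Number of observations (must be at least `p + 1`).
#' @param seed Optional integer seed.
#' @return Numeric `n` x `p` matrix with columns `V1..Vp`.
#' @export
simulate_factor_data <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "factor_model"))
  n <- as.integer(n)
  if (n < model$p + 1L) stop("need n >= p + 1", call. = FALSE)
  x <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, model$p),
                                     Sigma = model$sigma))
  colnames(x) <- paste0("V", seq_len(model$p))
  x
}

#' Enumerate the crossed simulation design grid
#'
#' Fully crosses the supplied factor levels and applies the structural
#' exclusion rule for single-factor conditions (no `rho` variation, no
#' cross-loadings). The default levels are the evaluation study's design:
#' k in \{1,3,5\}, n in \{250,500,1000\}, vpf in \{4,7\}, rho in
#' \{0,0.2,0.5\}, three primary and three cross-loading bins, giving
#' 324 multi-factor + 18 single-factor = 342 conditions.
#'
#' @param factors,sample_sizes,vpf,rho,primary,cross Level vectors.
#' @return A data frame, one row per condition, in deterministic order, with
#'   a `condition` id column.
#' @export
design_grid <- function(factors = c(1L, 3L, 5L),
                        sample_sizes = c(250L, 500L, 1000L),
                        vpf = c(4L, 7L),
                        rho = c(0, 0.2, 0.5),
                        primary = c("small", "medium", "large"),
                        cross = c("zero", "small", "medium")) {
  g <- expand.grid(k = as.integer(factors), n = as.integer(sample_sizes),
                   vpf = as.integer(vpf), rho = rho,
                   primary = primary, cross = cross,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- g$k > 1L | (g$rho == 0 & g$cross == "zero")
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty design grid", call. = FALSE)
  g <- g[order(g$k, g$n, g$vpf, g$rho, match(g$primary, c("small", "medium", "large")),
               match(g$cross, c("zero", "small", "medium"))), , drop = FALSE]
  rownames(g) <- NULL
  cbind(condition = seq_len(nrow(g)), g)
}
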