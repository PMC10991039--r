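# Front end: one fitting function returning a classed result, with the usual
# modelling-object methods.

#' Estimate the number of factors underlying a data set
#'
#' Applies one of three factor-retention criteria to a numeric data matrix:
#'
#' * `"cd"` — comparison data: sequential eigenvalue-RMSR comparison of
#'   simulated k-factor populations with a Mann-Whitney U stopping rule
#'   ([run_cd()]).
#' * `"cdf"` — comparison data forest: a random forest trained on features of
#'   comparison data sets under 1..`k_max` factors predicts the count
#'   ([run_cdf()]).
#' * `"ekc"` — empirical Kaiser criterion: sample eigenvalues against
#'   sample-size-adjusted references ([run_ekc()]); simulation settings are
#'   ignored.
#'
#' @param x Numeric data matrix or data frame, observations in rows.
#' @param method `"cd"`, `"cdf"` or `"ekc"`.
#' @param k_max Largest candidate number of factors (default 8).
#' @param alpha CD only: level of the internal U test (default 0.05).
#' @param n_rep Comparison data sets per factor solution (default 1000).
#' @param n_population Comparison population size (default 10000).
#' @param n_trees CDF only: forest size (default 500).
#' @param seed Optional integer master seed; sub-seeds for the generator, the
#'   replicate sampling and the forest are derived from it.
#' @param ... Further arguments passed to the method workhorse (e.g.
#'   `max_iterations`, `max_stalled`).
#' @return Object of class `"nfactors"`: `k_hat`, `method`, `diagnostics`
#'   (method-specific), `eigenvalues`, `settings`, `n`, `p`, `seed`, `call`.
#' @examples
#' m <- factor_model(matrix(runif(6, 0.65, 0.8), 6, 1))
#' x <- simulate_factor_data(m, n = 300, seed = 1)
#' n_factors(x, method = "ekc")
#' @export
n_factors <- function(x, method = c("cd", "cdf", "ekc"), k_max = 8L,
                      alpha = 0.05, n_rep = 1000L, n_population = 10000L,
                      n_trees = 500L, seed = NULL, ...) {
  method <- match.arg(method)
  x <- check_data_matrix(x)
  t0 <- proc.time()[["elapsed"]]
  fit <- switch(method,
    cd = run_cd(x, alpha = alpha, n_rep = n_rep,
                n_population = n_population, k_max = k_max, seed = seed, ...),
    cdf = run_cdf(x, k_max = k_max, n_rep = n_rep,
                  n_population = n_population, n_trees = n_trees,
                  seed = seed, ...),
    ekc = run_ekc(x)
  )
  settings <- switch(method,
    cd = list(alpha = alpha, n_rep = n_rep, n_population = n_population,
              k_max = k_max),
    cdf = list(n_rep = n_rep, n_population = n_population, k_max = k_max,
               n_trees = n_trees),
    ekc = list()
  )
  structure(list(
    k_hat = fit$k_hat,
    method = method,
    diagnostics = fit[setdiff(names(fit), "k_hat")],
    eigenvalues = eigen_profile(correlation_matrix(x)),
    settings = settings,
    n = nrow(x), p = ncol(x),
    seed = seed,
    elapsed = proc.time()[["elapsed"]] - t0,
    call = match.call()
  ), class = "nfactors")
}

#' @export
print.nfactors <- function(x, ...) {
  label <- c(cd = "comparison data", cdf = "comparison data forest",
             ekc = "empirical Kaiser criterion")[x$method]
  cat(sprintf("Factor retention by %s (%s)\n", label, x$method))
  cat(sprintf("  data: %d observations of %d variables\n", x$n, x$p))
  cat(sprintf("  estimated number of factors: %d\n", x$k_hat))
  if (x$method == "cd" && length(x$diagnostics$p_values)) {
    cat("  step p-values:",
        paste(formatC(x$diagnostics$p_values, digits = 3, format = "g"),
              collapse = ", "), "\n")
  }
  if (x$method == "cdf") {
    cat("  forest votes:",
        paste(formatC(x$diagnostics$votes, digits = 2, format = "f"),
              collapse = " "), "\n")
  }
  if (x$method == "ekc" && x$diagnostics$k_raw == 0L) {
    cat("  note: first eigenvalue below its reference (raw estimate 0, floored at 1)\n")
  }
  invisible(x)
}

#' @export
coef.nfactors <- function(object, ...) {
  c(k = object$k_hat)
}

#' @export
summary.nfactors <- function(object, ...) {
  structure(object, class = c("summary.nfactors", class(object)))
}

#' @export
print.summary.nfactors <- function(x, ...) {
  print.nfactors(x, ...)
  cat("\nEigenvalues of the sample correlation matrix:\n")
  print(round(x$eigenvalues, 3))
  if (x$method == "ekc") {
    cat("\nEKC reference values:\n")
    print(round(x$diagnostics$references, 3))
  }
  if (x$method == "cd") {
    means <- vapply(x$diagnostics$rmsr_distributions, mean, numeric(1L))
    cat("\nMean eigenvalue RMSR per factor solution:\n")
    print(round(stats::setNames(means, seq_along(means)), 4))
  }
  if (x$method == "cdf") {
    cat(sprintf("\nOut-of-bag accuracy of the internal forest: %.3f\n",
                x$diagnostics$oob_accuracy))
    print(stats::setNames(round(x$diagnostics$votes, 3),
                          seq_along(x$diagnostics$votes)))
  }
  if (length(x$settings)) {
    cat("\nSettings:",
        paste(names(x$settings), unlist(x$settings), sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a factor-retention result
#'
#' Scree plot of the sample eigenvalues with the estimate marked; EKC results
#' additionally show the reference curve, CD results the per-solution mean
#' RMSR, CDF results the forest vote distribution.
#'
#' @param x An [n_factors()] result.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.nfactors <- function(x, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (x$method != "ekc") graphics::par(mfrow = c(1, 2))
  graphics::plot(seq_along(x$eigenvalues), x$eigenvalues, type = "b",
                 xlab = "component", ylab = "eigenvalue",
                 main = sprintf("Scree (k_hat = %d)", x$k_hat), ...)
  graphics::abline(v = x$k_hat + 0.5, lty = 2)
  if (x$method == "ekc") {
    graphics::lines(seq_along(x$diagnostics$references),
                    x$diagnostics$references, col = 2, type = "b", pch = 3)
    graphics::legend("topright", legend = c("eigenvalues", "EKC reference"),
                     col = c(1, 2), pch = c(1, 3), bty = "n")
  } else if (x$method == "cd") {
    means <- vapply(x$diagnostics$rmsr_distributions, mean, numeric(1L))
    graphics::plot(seq_along(means), means, type = "b",
                   xlab = "factor solution", ylab = "mean eigenvalue RMSR",
                   main = "Comparison data fit")
  } else {
    graphics::barplot(x$diagnostics$votes,
                      names.arg = seq_along(x$diagnostics$votes),
                      xlab = "candidate k", ylab = "vote share",
                      main = "Forest votes")
  }
  invisible(x)
}
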