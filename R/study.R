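# Monte Carlo evaluation harness: run conditions x replications x methods on
# shared simulated data sets (paired design) and aggregate accuracy and bias.

#' Run a paired Monte Carlo evaluation of retention methods
#'
#' For every condition (row of `grid`) and replication, one population model
#' is drawn and one data set simulated from it; every method is then applied
#' to that same data set, so method comparisons are paired. All randomness
#' derives from `seed` via per-cell sub-seeds, making the run reproducible
#' and resumable: with `journal` set, each finished cell is appended as one
#' JSON line and already-journaled cells are skipped on re-run.
#'
#' @param grid Data frame of conditions as produced by [design_grid()] (or
#'   any subset of its rows).
#' @param replications Replications per condition.
#' @param methods Named list of method settings; each element is a list with
#'   at least `method` (`"cd"`, `"cdf"` or `"ekc"`) plus arguments for
#'   [n_factors()], e.g. `list(cd = list(method = "cd", alpha = .05,
#'   n_rep = 250))`.
#' @param seed Integer master seed.
#' @param journal Optional path to a JSON-lines journal file.
#' @param verbose Print one line per condition.
#' @return Data frame of study records: condition columns, `replication`,
#'   `method`, `k_true`, `k_hat`, `seconds`, `error`; `NULL` when every cell
#'   is already present in the journal.
#' @export
run_study <- function(grid, replications = 50L, methods, seed = 1L,
                      journal = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, replications >= 1L,
            is.list(methods), length(methods) >= 1L)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("methods must be a named list", call. = FALSE)
  }
  done <- character(0)
  if (!is.null(journal) && file.exists(journal)) {
    prev <- readLines(journal, warn = FALSE)
    done <- vapply(prev, function(l) {
      r <- jsonlite::fromJSON(l)
      paste(r$condition, r$replication, r$method, sep = "|")
    }, character(1L), USE.NAMES = FALSE)
  }
  records <- list()
  for (ci in seq_len(nrow(grid))) {
    cond <- grid[ci, , drop = FALSE]
    spec <- condition_spec(cond$k, cond$n, cond$vpf, cond$rho,
                           cond$primary, cond$cross)
    for (rep_i in seq_len(replications)) {
      cell_seed <- substream(seed, cond$condition * 10000L + rep_i)
      model <- build_population(spec, seed = substream(cell_seed, 1L))
      x <- simulate_factor_data(model, spec$n, seed = substream(cell_seed, 2L))
      for (mi in seq_along(methods)) {
        mname <- names(methods)[mi]
        key <- paste(cond$condition, rep_i, mname, sep = "|")
        if (key %in% done) next
        args <- methods[[mi]]
        args$x <- x
        args$seed <- substream(cell_seed, 10L + mi)
        t0 <- proc.time()[["elapsed"]]
        fit <- tryCatch(do.call(n_factors, args), error = function(e) e)
        secs <- proc.time()[["elapsed"]] - t0
        rec <- cbind(cond,
                     data.frame(replication = rep_i, method = mname,
                                k_true = spec$k,
                                k_hat = if (inherits(fit, "error")) NA_integer_
                                        else fit$k_hat,
                                seconds = secs,
                                error = if (inherits(fit, "error"))
                                          conditionMessage(fit) else NA_character_,
                                stringsAsFactors = FALSE))
        records[[length(records) + 1L]] <- rec
        if (!is.null(journal)) {
          cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE), "\n",
              file = journal, append = TRUE, sep = "")
        }
      }
    }
    if (verbose) {
      message(sprintf("condition %d/%d done", ci, nrow(grid)))
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Aggregate study records into accuracy and bias tables
#'
#' Exact arithmetic on counts: per group, the proportion of correct
#' estimates, the mean signed error (bias), and the under-/overfactoring
#' rates; `accuracy + underfactor_rate + overfactor_rate = 1`.
#'
#' @param records Data frame from [run_study()].
#' @param by Character vector of grouping columns (default `"method"`).
#' @return Data frame with one row per group: `accuracy`, `bias`,
#'   `underfactor_rate`, `overfactor_rate`, `n_cells`.
#' @export
aggregate_study <- function(records, by = "method") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  missing_keys <- setdiff(by, names(records))
  if (length(missing_keys)) {
    stop("unknown grouping key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  records <- records[!is.na(records$k_hat), , drop = FALSE]
  groups <- split(records, records[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(g[1L, by, drop = FALSE],
          data.frame(
            accuracy = mean(g$k_hat == g$k_true),
            bias = mean(g$k_hat - g$k_true),
            underfactor_rate = mean(g$k_hat < g$k_true),
            overfactor_rate = mean(g$k_hat > g$k_true),
            n_cells = nrow(g)))
  }))
  rownames(out) <- NULL
  out[do.call(order, unname(as.list(out[by]))), , drop = FALSE]
}

#' Agreement analysis between two retention methods
#'
#' Pairs the records of two methods by (condition, replication) and reports
#' the overall agreement rate, the accuracy of the shared estimate given
#' agreement, and a breakdown by the level of disagreement
#' `k_hat_a - k_hat_b` with each method's conditional accuracy.
#'
#' @param records Data frame from [run_study()].
#' @param method_a,method_b Method names as used in `run_study`'s `methods`.
#' @return List with `agreement_rate`, `accuracy_given_agreement`,
#'   `n_pairs`, and `by_difference` (data frame: difference level, relative
#'   frequency, conditional accuracy of each method).
#' @export
agreement_analysis <- function(records, method_a, method_b) {
  a <- records[records$method == method_a & !is.na(records$k_hat), ]
  b <- records[records$method == method_b & !is.na(records$k_hat), ]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("no records for one of the requested methods", call. = FALSE)
  }
  key <- function(d) paste(d$condition, d$replication, sep = "|")
  m <- merge(a[, c("condition", "replication", "k_true", "k_hat")],
             b[, c("condition", "replication", "k_hat")],
             by = c("condition", "replication"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("methods share no paired cells", call. = FALSE)
  agree <- m$k_hat_a == m$k_hat_b
  diffs <- m$k_hat_a - m$k_hat_b
  by_diff <- do.call(rbind, lapply(sort(unique(diffs)), function(d) {
    s <- m[diffs == d, ]
    data.frame(difference = d,
               frequency = nrow(s) / nrow(m),
               accuracy_a = mean(s$k_hat_a == s$k_true),
               accuracy_b = mean(s$k_hat_b == s$k_true))
  }))
  list(agreement_rate = mean(agree),
       accuracy_given_agreement =
         if (any(agree)) mean(m$k_hat_a[agree] == m$k_true[agree]) else NaN,
       n_pairs = nrow(m),
       by_difference = by_diff)
}
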