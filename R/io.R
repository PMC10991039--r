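# Readers/writers: delimited data matrices in, JSON retention results out.

#' Read a numeric data matrix from delimited text
#'
#' Reads CSV/TSV-style files, auto-detecting a header row, and validates the
#' result: every cell numeric, no missing values (errors name the offending
#' row and column), at least 3 columns, no constant columns.
#'
#' @param path File path.
#' @param delimiter Field separator (default `","`).
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect (default).
#' @return Validated numeric matrix.
#' @export
read_data_matrix <- function(path, delimiter = ",", header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) | !nzchar(trimws(col)))
      stop(sprintf("non-numeric or empty cell at row %d, column %d",
                   if (length(bad)) bad[1L] else 1L, j), call. = FALSE)
    }
  }
  check_data_matrix(as.matrix(df))
}

#' Write a retention result to JSON
#'
#' Serializes an [n_factors()] result (method, estimate, settings echo, seed,
#' compact diagnostics) with a schema version, at 12 significant digits.
#'
#' @param result An `"nfactors"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_retention <- function(result, path) {
  stopifnot(inherits(result, "nfactors"))
  diag <- switch(result$method,
    cd = list(p_values = result$diagnostics$p_values,
              rmsr_means = vapply(result$diagnostics$rmsr_distributions,
                                  mean, numeric(1L)),
              censored = result$diagnostics$censored),
    cdf = list(votes = result$diagnostics$votes,
               oob_accuracy = result$diagnostics$oob_accuracy),
    ekc = list(k_raw = result$diagnostics$k_raw,
               references = result$diagnostics$references,
               eigenvalues = result$diagnostics$eigenvalues)
  )
  doc <- list(schema = "cdforest/retention/1",
              method = result$method,
              k_hat = result$k_hat,
              n = result$n, p = result$p,
              settings = result$settings,
              seed = result$seed,
              diagnostics = diag)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 12, null = "null")
  invisible(path)
}

#' Read a study configuration file
#'
#' JSON (or YAML, when the yaml package is available) configuration for
#' [design_grid()] / [run_study()]: keys `factors`, `sample_sizes`, `vpf`,
#' `rho`, `primary_bins`, `cross_bins`, `replications`, `seed`; omitted keys
#' fall back to the study defaults. Unknown keys are rejected.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return List with elements `grid` (from [design_grid()]), `replications`,
#'   `seed`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  known <- c("factors", "sample_sizes", "vpf", "rho", "primary_bins",
             "cross_bins", "replications", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- formals(design_grid)
  grid <- design_grid(
    factors = cfg$factors %||% eval(defaults$factors),
    sample_sizes = cfg$sample_sizes %||% eval(defaults$sample_sizes),
    vpf = cfg$vpf %||% eval(defaults$vpf),
    rho = cfg$rho %||% eval(defaults$rho),
    primary = cfg$primary_bins %||% eval(defaults$primary),
    cross = cfg$cross_bins %||% eval(defaults$cross)
  )
  list(grid = grid,
       replications = as.integer(cfg$replications %||% 500L),
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
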