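# Internal helpers: seeding, validation.

# Derive a reproducible sub-stream seed from a master seed and an integer key.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it.
substream <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  m <- 2147483629
  as.integer((as.double(seed) %% m * 48271 + as.double(key) * 1009 + 17) %% m)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Validate an n x p data matrix: numeric, complete, every column varying.
check_data_matrix <- function(x, min_cols = 3L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data must be numeric", call. = FALSE)
  if (ncol(x) < min_cols) {
    stop(sprintf("data must have at least %d columns, got %d", min_cols, ncol(x)),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0)) {
    stop(sprintf("column %d has zero variance", which(v <= 0)[1L]), call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

#' Pearson correlation matrix with validation
#'
#' Thin wrapper around [stats::cor()] that first checks the input is a
#' complete numeric matrix with no constant columns, so degenerate inputs
#' fail loudly instead of propagating `NaN` into eigen decompositions.
#'
#' @param data Numeric matrix (observations in rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  data <- check_data_matrix(data, min_cols = 2L)
  r <- stats::cor(data)
  (r + t(r)) / 2
}
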