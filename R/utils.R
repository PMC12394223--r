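#' @importFrom stats rnorm setNames
#' @importFrom utils count.fields head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ke_parameter_error(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    ke_parameter_error(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(as.numeric(x))
}

# Row-wise L2 normalization; cosine similarity is undefined at zero, so
# zero-norm rows are rejected with the offending rows named.
l2_normalize_rows <- function(x, context = "matrix") {
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm == 0 | !is.finite(nrm))
  if (length(bad) > 0L) {
    ids <- rownames(x)[bad] %||% as.character(bad)
    ke_input_error(sprintf(
      "zero or non-finite norm in row(s) of %s: %s",
      context, paste(head(ids, 5L), collapse = ", ")))
  }
  x / nrm
}

# n_a x n_b cosine-similarity matrix between the rows of two matrices.
cosine_similarity <- function(a, b, context_a = "query", context_b = "bank") {
  if (ncol(a) != ncol(b))
    ke_input_error(sprintf(
      "dimension mismatch: %s has d=%d but %s has d=%d",
      context_a, ncol(a), context_b, ncol(b)))
  tcrossprod(l2_normalize_rows(a, context_a), l2_normalize_rows(b, context_b))
}

row_max <- function(x) apply(x, 1L, max)

# Independent deterministic substream seeds derived from one master seed.
# Kept below 2^31 - 1; exact in double arithmetic (< 2^53).
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + stream * 65537) %% 2147483629)
}
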