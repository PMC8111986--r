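# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cosine similarity between two non-negative vectors
#' @param a,b numeric vectors of equal length.
#' @return scalar in [-1, 1]; NA if either vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) abort("'%s' must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("'%s' must have row and column names", what)
  invisible(x)
}

# round half up (away from zero for positive x), fixed number of decimals;
# base round() uses round-half-even which does not reproduce printed tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# per-sample rank normalization to (0, 1]; ties get average ranks
rank_normalize <- function(x) {
  apply(x, 2, function(v) rank(v, ties.method = "average") / length(v))
}

# deterministic sub-seed derivation, kept below 2^31 (double arithmetic:
# integer multiplication would overflow)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483587)
}
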