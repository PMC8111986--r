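# 96-trinucleotide-context machinery and a synthetic reference signature set.

#' The canonical 96 trinucleotide mutation contexts
#'
#' Pyrimidine-centred single-base substitutions (C>A, C>G, C>T, T>A, T>C,
#' T>G) in each of the 16 flanking-base combinations, encoded as e.g.
#' `"A[C>T]G"`. Order: substitution-major, then 5' base, then 3' base,
#' both alphabetical.
#'
#' @return character vector of length 96.
#' @export
trinucleotide_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (b5 in bases) for (b3 in bases)
    out <- c(out, sprintf("%s[%s]%s", b5, s, b3))
  out
}

#' Synthetic reference mutational signatures
#'
#' A deterministic, fully synthetic set of 96-context probability profiles
#' used as the packaged reference for simulation and cosine-match
#' reporting. Each signature concentrates its mass on a distinct region of
#' the context spectrum (a discretized Gaussian bump on the context index
#' plus a small uniform floor), so pairwise cosines are low and recovery
#' experiments are well-posed. These are NOT empirical catalogue-derived
#' signatures; substitute a real reference table (96 rows, one column per
#' signature, columns summing to 1) for biological interpretation.
#'
#' @param n number of signatures (default 5, named `SIG_A` ...).
#' @param width bump width in context-index units (default 7).
#' @return 96-by-n column-stochastic matrix with context rownames.
#' @export
reference_signatures <- function(n = 5, width = 7) {
  ctx <- trinucleotide_contexts()
  centers <- seq(8, 88, length.out = n)
  sig <- vapply(centers, function(ce) {
    d <- abs(seq_len(96) - ce)
    d <- pmin(d, 96 - d)  # wrap so end signatures are not truncated
    p <- exp(-d^2 / (2 * width^2)) + 0.002
    p / sum(p)
  }, numeric(96))
  dimnames(sig) <- list(ctx, paste0("SIG_", LETTERS[seq_len(n)]))
  sig
}

#' Tabulate a mutation catalogue into 96-context counts
#'
#' @param catalog MAF-minimal data.frame with `Tumor_Sample_Barcode` and a
#'   `context96` column holding codes from [trinucleotide_contexts()]
#'   (records with missing context are ignored).
#' @param samples optional character vector fixing the column order (and
#'   including mutation-free samples as zero columns).
#' @return 96-by-sample integer count matrix.
#' @export
context_count_matrix <- function(catalog, samples = NULL) {
  ctx <- trinucleotide_contexts()
  if (is.null(samples)) samples <- sort(unique(catalog$Tumor_Sample_Barcode))
  keep <- !is.na(catalog$context96)
  bad <- setdiff(unique(catalog$context96[keep]), ctx)
  if (length(bad) > 0) abort("invalid context codes: %s", paste(utils::head(bad, 5), collapse = ", "))
  tab <- table(factor(catalog$context96[keep], levels = ctx),
               factor(catalog$Tumor_Sample_Barcode[keep], levels = samples))
  mat <- matrix(as.integer(tab), 96, length(samples), dimnames = list(ctx, samples))
  mat
}
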