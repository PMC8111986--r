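#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT format: one gene set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes duplicated within a
#' set are collapsed to one occurrence (first kept).
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of gene identifiers, with a
#'   `descriptions` attribute (named character vector). An empty file yields
#'   an empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort("malformed GMT line %d: fewer than 3 tab-separated fields", i)
    nm <- fields[[1]]
    if (nm %in% names(sets)) abort("duplicate gene-set name '%s' (line %d)", nm, i)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes
    descs[[nm]] <- fields[[2]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample GSEA enrichment scores
#'
#' Computes per-sample, per-set enrichment scores using the rank-weighted
#' running-sum (integral) form. For each sample, genes are ranked by
#' decreasing expression (ties broken by gene identifier, lexicographically,
#' for bit-reproducibility); with descending-rank weights
#' \eqn{r_j = N - \mathrm{position}_j + 1}, the score is
#' \deqn{ES = \sum_i \left( P_{in}(i) - P_{out}(i) \right)}
#' where \eqn{P_{in}} is the weighted in-set cumulative sum
#' (weights \eqn{r_j^\alpha}, normalized to the in-set total) and
#' \eqn{P_{out}} steps by \eqn{1/(N-|S|)} at out-of-set genes.
#'
#' Because the score depends only on ranks, it is invariant under any
#' strictly monotone transform of a sample's expression values.
#'
#' @param expr numeric gene-by-sample matrix with dimnames; any values on a
#'   non-negative (e.g. log2) scale.
#' @param sets named list of character vectors (see [read_gmt()]).
#' @param alpha rank weight exponent (default 0.25; `alpha = 0` gives the
#'   unweighted Kolmogorov-Smirnov-style score).
#' @param normalize one of `"none"`, `"global-range"` (divide all scores by
#'   the global max-min range) or `"z-by-set"` (per-set z-score across
#'   samples).
#' @return a set-by-sample numeric matrix. Sets with no genes in the
#'   expression universe get `NA` rows and are listed in the
#'   `"set_errors"` attribute instead of failing globally. A set covering
#'   the whole universe is an error (the out-of-set distribution is
#'   undefined).
#' @export
ssgsea_scores <- function(expr, sets,
                          alpha = 0.25,
                          normalize = c("none", "global-range", "z-by-set")) {
  assert_matrix(expr, "expr")
  normalize <- match.arg(normalize)
  if (alpha < 0) abort("alpha must be >= 0")
  if (length(sets) == 0) abort("empty gene-set collection")
  genes <- rownames(expr)
  n <- length(genes)
  memb <- lapply(sets, function(s) genes %in% s)
  sizes <- vapply(memb, sum, integer(1))
  full <- names(sets)[sizes == n]
  if (length(full) > 0)
    abort("gene set(s) equal to the full universe: %s", paste(full, collapse = ", "))
  errs <- names(sets)[sizes == 0]
  if (length(errs) > 0)
    warning(sprintf("gene set(s) with empty intersection scored NA: %s",
                    paste(errs, collapse = ", ")), call. = FALSE)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    # decreasing expression, lexicographic gene-id tiebreak
    ord <- order(-expr[, s], genes, method = "radix")
    w <- (n - seq_len(n) + 1)^alpha            # descending-rank weight at each position
    for (k in seq_along(sets)) {
      if (sizes[[k]] == 0) next
      inset <- memb[[k]][ord]
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (n - sizes[[k]])
      scores[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalize == "global-range") {
    rng <- range(scores, na.rm = TRUE)
    scores <- scores / (rng[2] - rng[1])
  } else if (normalize == "z-by-set") {
    scores <- t(scale(t(scores)))
    dimnames(scores) <- list(names(sets), colnames(expr))
  }
  attr(scores, "set_errors") <- errs
  attr(scores, "alpha") <- alpha
  attr(scores, "normalize") <- normalize
  scores
}
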