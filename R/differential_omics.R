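# Differential analysis per omics layer and preranked GSEA.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector in `[0, 1]`; `NaN` is an error.
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.nan(pvals))) abort("NaN p-values")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group differential analysis of a feature matrix
#'
#' Per-feature two-sample test (Welch t by default, or Wilcoxon rank-sum),
#' BH adjustment across all tested features, and a pass flag using the
#' conventional thresholds: adjusted p below `fdr` AND absolute log
#' fold-change above `lfc`. The matrix is assumed to be on a log scale so
#' that `logFC = mean(group A) - mean(group B)`, A being the first factor
#' level of `groups` (reported in the `contrast` attribute). The
#' fold-change threshold is applied two-sidedly (both up- and down-regulated
#' features are reported, with `direction`).
#'
#' Features with zero variance in both groups get a guarded p-value (1 when
#' the means are equal, 0 otherwise) and `zero_variance = TRUE`.
#'
#' @param mat feature-by-sample numeric matrix (log scale).
#' @param groups 2-level factor/character vector along columns.
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc absolute log fold-change threshold (default 1.0; use 0 to
#'   disable, e.g. for protein data filtered on p alone).
#' @return data.frame: `feature`, `logFC`, `p`, `adj_p`, `pass`,
#'   `direction`, `zero_variance`; `contrast` attribute records the group
#'   order.
#' @export
differential_expression <- function(mat, groups,
                                    test = c("welch_t", "wilcoxon"),
                                    fdr = 0.05, lfc = 1.0) {
  assert_matrix(mat, "mat")
  test <- match.arg(test)
  g <- factor(groups)
  if (nlevels(g) != 2) abort("groups must have exactly 2 levels")
  if (any(table(g) < 2)) abort("need >= 2 samples per group")
  a <- g == levels(g)[1]; b <- !a
  ma <- rowMeans(mat[, a, drop = FALSE]); mb <- rowMeans(mat[, b, drop = FALSE])
  na <- sum(a); nb <- sum(b)
  va <- apply(mat[, a, drop = FALSE], 1, stats::var)
  vb <- apply(mat[, b, drop = FALSE], 1, stats::var)
  zero <- va + vb == 0
  if (test == "welch_t") {
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  } else {
    p <- apply(mat, 1, function(x)
      suppressWarnings(stats::wilcox.test(x[a], x[b], exact = FALSE)$p.value))
    p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  }
  adj <- benjamini_hochberg(p)
  logfc <- ma - mb
  out <- data.frame(feature = rownames(mat), logFC = logfc, p = p, adj_p = adj,
                    pass = adj < fdr & abs(logfc) > lfc,
                    direction = ifelse(logfc > 0, "up", "down"),
                    zero_variance = zero, row.names = NULL)
  attr(out, "contrast") <- sprintf("%s - %s", levels(g)[1], levels(g)[2])
  attr(out, "test") <- test
  out
}

# weighted-KS running-sum ES on a decreasing ranking; returns ES at the
# maximum absolute deviation plus the deviation profile's argmax
gsea_es <- function(stat_sorted, inset, weight) {
  nr <- sum(abs(stat_sorted[inset])^weight)
  if (nr == 0) return(list(es = 0, peak = 0L))
  inc <- ifelse(inset, abs(stat_sorted)^weight / nr, -1 / (length(inset) - sum(inset)))
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak)
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a user-supplied
#' ranking: features are sorted by decreasing statistic, the running sum
#' gains `|stat|^weight` (normalized within the set) at set members and
#' loses `1/(N - |S|)` elsewhere, and the enrichment score is the running
#' sum at its maximum absolute deviation. Significance comes from
#' gene-label permutation: random sets of the same size drawn from the
#' ranking. NES divides ES by the mean same-sign permutation ES; the FDR is
#' estimated sign-stratified across all sets, GSEA-style.
#'
#' @param stats named numeric vector (no duplicated names).
#' @param sets named list of gene sets; each must intersect the universe.
#' @param n_perm number of permutations (>= 10).
#' @param weight exponent on `|stat|` (default 1; 0 gives the unweighted
#'   KS statistic).
#' @param seed integer seed.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `fdr`,
#'   `leading_edge` (comma-separated gene ids).
#' @export
preranked_gsea <- function(stats, sets, n_perm = 1000, weight = 1, seed = 1) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    abort("stats must be a named vector without duplicate features")
  if (n_perm < 10) abort("n_perm must be >= 10")
  ord <- order(-stats, names(stats), method = "radix")
  s <- stats[ord]
  genes <- names(s)
  n <- length(s)
  sizes <- vapply(sets, function(x) sum(genes %in% x), integer(1))
  if (any(sizes == 0)) abort("set(s) with empty intersection: %s",
                             paste(names(sets)[sizes == 0], collapse = ", "))
  if (any(sizes == n)) abort("set equal to the full universe")
  set.seed(seed)
  res <- vector("list", length(sets))
  perm_nes <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    inset <- genes %in% sets[[k]]
    obs <- gsea_es(s, inset, weight)
    m <- sizes[[k]]
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, m)
      memb <- logical(n); memb[idx] <- TRUE
      gsea_es(s, memb, weight)$es
    }, numeric(1))
    same <- if (obs$es >= 0) perm[perm >= 0] else perm[perm < 0]
    pnom <- if (length(same) == 0) 1 / n_perm else
      (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    denom <- if (length(same) == 0) abs(obs$es) else mean(abs(same))
    nes <- if (denom == 0) 0 else obs$es / denom
    mpos <- if (any(perm >= 0)) mean(perm[perm >= 0]) else 1
    mneg <- if (any(perm < 0)) mean(-perm[perm < 0]) else 1
    pn <- ifelse(perm >= 0, perm / max(mpos, 1e-12), perm / max(mneg, 1e-12))
    le <- if (obs$es >= 0) genes[seq_len(obs$peak)][inset[seq_len(obs$peak)]]
          else genes[obs$peak:n][inset[obs$peak:n]]
    res[[k]] <- data.frame(set = names(sets)[k], size = m, ES = obs$es,
                           NES = nes, p = pnom,
                           leading_edge = paste(le, collapse = ","))
    perm_nes[[k]] <- pn
  }
  out <- do.call(rbind, res)
  allp <- unlist(perm_nes)
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$NES[i]
    if (nes >= 0) {
      num <- mean(allp[allp >= 0] >= nes)
      den <- mean(out$NES[out$NES >= 0] >= nes)
    } else {
      num <- mean(allp[allp < 0] <= nes)
      den <- mean(out$NES[out$NES < 0] <= nes)
    }
    min(1, max(0, ifelse(den == 0, 1, num / den)))
  }, numeric(1))
  out[, c("set", "size", "ES", "NES", "p", "fdr", "leading_edge")]
}
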