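# Copy-number burden, arm-level aneuploidy, mutation-frequency filtering,
# mutational-signature extraction and group-wise alteration tests.

#' Read / write SEG-format copy-number segments
#'
#' Tab-separated with header
#' `Sample Chromosome Start End Num_Probes Segment_Mean`; coordinates are
#' 1-based inclusive base pairs and `Segment_Mean` is log2 relative copy
#' number.
#'
#' @param path file path.
#' @return data.frame with the six columns above.
#' @export
read_seg <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  if (!all(need %in% names(seg)))
    abort("SEG file missing columns: %s", paste(setdiff(need, names(seg)), collapse = ", "))
  if (any(seg$End < seg$Start)) abort("SEG file has segments with End < Start")
  seg[need]
}

#' @rdname read_seg
#' @param seg segment data.frame.
#' @export
write_seg <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged chromosome-arm coordinate table (hg38, approximate)
#'
#' Approximate cytoband-derived arm boundaries for chr1-22 and chrX. The p
#' arms of the acrocentric chromosomes (13, 14, 15, 21, 22) are excluded,
#' giving 41 arms.
#'
#' @return data.frame `arm`, `chromosome`, `start`, `end` (1-based bp).
#' @export
load_arm_table <- function() {
  path <- system.file("extdata", "hg38_arms.tsv", package = "immunoclass")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# length-weighted mean seg_mean of segments overlapping [start, end];
# returns NA when nothing overlaps
interval_weighted_mean <- function(seg_chr, start, end) {
  ov_start <- pmax(seg_chr$Start, start)
  ov_end <- pmin(seg_chr$End, end)
  w <- pmax(0, ov_end - ov_start + 1)
  if (sum(w) == 0) return(NA_real_)
  sum(w * seg_chr$Segment_Mean) / sum(w)
}

#' Gene-level copy-number gain/loss calls
#'
#' Each gene's value is the length-weighted mean `Segment_Mean` over the
#' segments overlapping it; values strictly above `gain_thr` are gains and
#' strictly below `loss_thr` losses (the thresholds themselves are
#' neutral). Genes with no overlapping segment in a sample are neutral and
#' flagged missing.
#'
#' @param segments SEG data.frame (see [read_seg()]).
#' @param gene_coords data.frame `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive, same build as the segments).
#' @param gain_thr,loss_thr call thresholds (defaults +0.3 / -0.3).
#' @return character gene-by-sample matrix in `{"gain","loss","neutral"}`
#'   with a logical `"missing"` attribute matrix of the same shape.
#' @export
call_gains_losses <- function(segments, gene_coords, gain_thr = 0.3, loss_thr = -0.3) {
  samples <- unique(segments$Sample)
  calls <- matrix("neutral", nrow(gene_coords), length(samples),
                  dimnames = list(gene_coords$gene, samples))
  miss <- matrix(FALSE, nrow(gene_coords), length(samples),
                 dimnames = dimnames(calls))
  for (s in samples) {
    seg_s <- segments[segments$Sample == s, ]
    for (g in seq_len(nrow(gene_coords))) {
      seg_chr <- seg_s[seg_s$Chromosome == gene_coords$chromosome[g], ]
      v <- interval_weighted_mean(seg_chr, gene_coords$start[g], gene_coords$end[g])
      if (is.na(v)) {
        miss[g, s] <- TRUE
      } else if (v > gain_thr) {
        calls[g, s] <- "gain"
      } else if (v < loss_thr) {
        calls[g, s] <- "loss"
      }
    }
  }
  attr(calls, "missing") <- miss
  calls
}

#' Fraction of the genome altered and segment counts
#'
#' Copy-number burden per sample: the fraction of covered bases lying in
#' segments whose log2 copy number deviates from baseline ploidy by more
#' than `thr` in absolute value, together with the total number of
#' segments in the profile.
#'
#' @param segments SEG data.frame.
#' @param thr deviation threshold (default 0.1; strict inequality).
#' @return data.frame `sample`, `fraction_altered`, `n_segments`.
#' @export
fraction_genome_altered <- function(segments, thr = 0.1) {
  if (nrow(segments) == 0) abort("empty segment table")
  out <- lapply(split(segments, segments$Sample), function(seg) {
    len <- seg$End - seg$Start + 1
    if (sum(len) == 0) abort("sample %s has zero total segment length", seg$Sample[1])
    data.frame(sample = seg$Sample[1],
               fraction_altered = sum(len[abs(seg$Segment_Mean) > thr]) / sum(len),
               n_segments = nrow(seg))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Arm-level aneuploidy score
#'
#' For each chromosome arm, the arm value is the length-weighted mean
#' `Segment_Mean` over the arm; the arm counts as altered when the absolute
#' arm value strictly exceeds `arm_thr`. The score is the number of altered
#' (amplified or deleted) arms. Arms with no covered bases in a sample are
#' skipped and reported in the `"skipped_arms"` attribute.
#'
#' @param segments SEG data.frame.
#' @param arms arm table (default [load_arm_table()]).
#' @param arm_thr arm-call threshold (default 0.1).
#' @return data.frame `sample`, `aneuploidy_score`.
#' @export
aneuploidy_score <- function(segments, arms = load_arm_table(), arm_thr = 0.1) {
  samples <- unique(segments$Sample)
  skipped <- list()
  score <- vapply(samples, function(s) {
    seg_s <- segments[segments$Sample == s, ]
    vals <- vapply(seq_len(nrow(arms)), function(a) {
      seg_chr <- seg_s[seg_s$Chromosome == arms$chromosome[a], ]
      interval_weighted_mean(seg_chr, arms$start[a], arms$end[a])
    }, numeric(1))
    if (any(is.na(vals))) skipped[[s]] <<- arms$arm[is.na(vals)]
    sum(abs(vals) > arm_thr, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(sample = samples, aneuploidy_score = as.integer(score),
                    row.names = NULL)
  attr(out, "skipped_arms") <- skipped
  out
}

#' Recurrently mutated genes above a cohort frequency
#'
#' Genes carrying a non-silent mutation in strictly more than
#' `min_freq * n_samples` samples. Multiple records of a gene within one
#' sample count once.
#'
#' @param catalog minimal MAF data.frame with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode` and `Variant_Classification`.
#' @param n_samples cohort size (the denominator; the catalog may omit
#'   unmutated samples).
#' @param min_freq frequency threshold (default 0.05, strict `>`).
#' @return character vector of gene symbols.
#' @export
mutation_frequency_filter <- function(catalog, n_samples, min_freq = 0.05) {
  if (n_samples <= 0) abort("n_samples must be > 0")
  if (nrow(catalog) == 0) return(character(0))
  silent <- c("Silent", "Synonymous", "3'UTR", "5'UTR", "Intron", "IGR", "RNA")
  cat2 <- catalog[!catalog$Variant_Classification %in% silent, ]
  if (nrow(cat2) == 0) return(character(0))
  per_gene <- tapply(cat2$Tumor_Sample_Barcode, cat2$Hugo_Symbol,
                     function(x) length(unique(x)))
  sort(names(per_gene)[per_gene > min_freq * n_samples])
}

#' Extract mutational signatures from 96-context catalogues
#'
#' Decomposes a 96-context-by-sample mutation count matrix into `k`
#' signatures by KL-divergence NMF (the same multiplicative-update engine
#' as the expression factorization). Signature columns are normalized to
#' probability profiles (sum 1) with exposures rescaled so that
#' `signatures %*% exposures` still reconstructs the counts in
#' expectation. Each extracted signature is matched by cosine similarity
#' against a reference signature table.
#'
#' @param context_counts 96-by-sample integer matrix; all-zero sample
#'   columns are dropped with a warning.
#' @param k number of signatures; must be < number of retained samples.
#' @param n_restarts,seed,max_iter passed to the NMF engine.
#' @param reference 96-by-r reference profiles (default
#'   [reference_signatures()]).
#' @return list with `signatures` (96 x k, column-stochastic), `exposures`
#'   (k x samples, >= 0), `match` (data.frame: signature, best reference,
#'   cosine), and the underlying `factor_model`.
#' @export
extract_mutational_signatures <- function(context_counts, k, n_restarts = 5,
                                          seed = 1, max_iter = 500,
                                          reference = reference_signatures()) {
  assert_matrix(context_counts, "context_counts")
  if (nrow(context_counts) != 96) abort("context_counts must have 96 rows")
  zero <- colSums(context_counts) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero sample column(s)", sum(zero)), call. = FALSE)
    context_counts <- context_counts[, !zero, drop = FALSE]
  }
  if (k >= ncol(context_counts)) abort("k must be < number of samples with mutations")
  # rows never observed would stall multiplicative updates; keep matrix dense
  x <- context_counts + 1e-9
  fit <- nmf(x, k, n_restarts = n_restarts, max_iter = max_iter, seed = seed)
  sig <- fit$W  # already unit-L1 columns
  expo <- fit$H
  dimnames(sig) <- list(rownames(context_counts), paste0("signature", seq_len(k)))
  dimnames(expo) <- list(colnames(sig), colnames(context_counts))
  match <- do.call(rbind, lapply(seq_len(k), function(j) {
    cs <- apply(reference, 2, cosine_similarity, b = sig[, j])
    data.frame(signature = colnames(sig)[j],
               best_reference = colnames(reference)[which.max(cs)],
               cosine = max(cs))
  }))
  list(signatures = sig, exposures = expo, match = match, model = fit)
}

#' Group-wise alteration contingency tests
#'
#' For each feature (gene-level CNV call or mutation flag), tests whether
#' the altered/not-altered split differs between groups with a Pearson
#' chi-square on the 2-by-g table, falling back to Fisher's exact test
#' when any expected count is below 5. Features altered in zero samples
#' are skipped; p-values are BH-adjusted across the tested features.
#'
#' @param altered logical feature-by-sample matrix.
#' @param groups group labels along columns (>= 2 groups).
#' @return data.frame `feature`, `test`, `p`, `q` plus per-group altered
#'   counts.
#' @export
differential_alteration_test <- function(altered, groups) {
  if (!is.logical(altered)) abort("'altered' must be a logical matrix")
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need >= 2 groups")
  keep <- rowSums(altered) > 0
  if (!any(keep)) abort("no feature is altered in any sample")
  rows <- lapply(rownames(altered)[keep], function(f) {
    tab <- table(factor(altered[f, ], levels = c(FALSE, TRUE)), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test <- "chi_square"
    }
    cnt <- as.list(tab[2, ])
    names(cnt) <- paste0("altered_", levels(g))
    cbind(data.frame(feature = f, test = test, p = p), as.data.frame(cnt))
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Leukocyte-fraction vs copy-number correlation
#'
#' Spearman rank correlation (average ranks for ties) between leukocyte
#' fraction and the number of copy-number segments, per group and pooled.
#'
#' @param leukocyte_fraction,n_segments paired numeric vectors.
#' @param groups optional group labels (per-group results require >= 4
#'   pairs per group).
#' @return data.frame `group`, `n`, `rho`, `p` (pooled row labelled
#'   `"all"`).
#' @export
leukocyte_cnv_correlation <- function(leukocyte_fraction, n_segments, groups = NULL) {
  if (length(leukocyte_fraction) != length(n_segments))
    abort("input vectors differ in length")
  if (!all(is.finite(leukocyte_fraction)) || !all(is.finite(n_segments)))
    abort("inputs must be finite")
  one <- function(x, y, label) {
    if (length(x) < 4) abort("group '%s' has fewer than 4 pairs", label)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      abort("constant vector in group '%s'", label)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(group = label, n = length(x), rho = unname(ct$estimate), p = ct$p.value)
  }
  res <- one(leukocyte_fraction, n_segments, "all")
  if (!is.null(groups)) {
    for (lev in sort(unique(as.character(groups)))) {
      sel <- groups == lev
      res <- rbind(res, one(leukocyte_fraction[sel], n_segments[sel], lev))
    }
  }
  rownames(res) <- NULL
  res
}
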