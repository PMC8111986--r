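# Immune-class discovery on exemplar genes and projection onto new cohorts.

#' Consensus clustering of samples by resampled hierarchical clustering
#'
#' Repeatedly subsamples the cohort, clusters the subsample by average-linkage
#' hierarchical clustering (over the supplied feature rows, typically
#' exemplar genes), and accumulates how often each sample pair lands in the
#' same cluster. The consensus matrix is the co-assignment count divided by
#' the co-sampling count; the final partition cuts an average-linkage tree
#' of 1 - consensus at `k_clusters`.
#'
#' Two sample-distance modes are available. `"euclidean"` (default) is the
#' plain Euclidean distance on the supplied features and is the right
#' choice when those features carry the class signal in their level, e.g.
#' exemplar-gene rows of a per-sample transcriptome-rank-normalized matrix
#' (the space [project_cohort()] also operates in). `"pearson"` is
#' 1 - Pearson correlation between samples after median-centering each
#' feature row; it keys on deviation shape rather than level, which suits
#' heterogeneous marker panels but cannot separate classes whose features
#' differ mainly by a common scale.
#'
#' @param expr feature-by-sample matrix (rows restricted to exemplar genes).
#'   Constant rows carry no information for either distance and are dropped
#'   with a warning; if all rows are constant this is an error.
#' @param k_clusters number of clusters (default 2: immune vs the rest).
#' @param n_resamples resampling iterations (default 100).
#' @param sample_fraction fraction of samples per iteration (default 0.8);
#'   with `sample_fraction = 1` every iteration sees the full cohort and
#'   consensus entries are exactly 0 or 1.
#' @param seed integer seed.
#' @param dist_method `"euclidean"` or `"pearson"` (see Details).
#' @return list with `consensus` (sample-by-sample, symmetric, unit
#'   diagonal), `partition` (named integer vector) and the call parameters.
#' @export
consensus_cluster <- function(expr, k_clusters = 2, n_resamples = 100,
                              sample_fraction = 0.8, seed = 1,
                              dist_method = c("euclidean", "pearson")) {
  assert_matrix(expr, "expr")
  dist_method <- match.arg(dist_method)
  n <- ncol(expr)
  if (n < 2 * k_clusters) abort("need at least 2*k_clusters samples")
  sds <- apply(expr, 1, stats::sd)
  if (all(sds == 0)) abort("all feature rows are constant")
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant feature rows", sum(sds == 0)), call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (dist_method == "pearson")
    expr <- expr - apply(expr, 1, stats::median)
  sample_dist <- function(cols) {
    if (dist_method == "pearson")
      stats::as.dist(1 - stats::cor(expr[, cols, drop = FALSE]))
    else stats::dist(t(expr[, cols, drop = FALSE]))
  }
  set.seed(seed)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  m <- max(k_clusters + 1, ceiling(sample_fraction * n))
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m))
    cl <- stats::cutree(stats::hclust(sample_dist(idx), "average"), k_clusters)
    tog[idx, idx] <- tog[idx, idx] + 1
    co[idx, idx] <- co[idx, idx] + outer(cl, cl, "==")
  }
  cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(expr), colnames(expr))
  part <- stats::cutree(stats::hclust(stats::as.dist(1 - cons), "average"), k_clusters)
  names(part) <- colnames(expr)
  list(consensus = cons, partition = part, k_clusters = k_clusters,
       n_resamples = n_resamples, sample_fraction = sample_fraction, seed = seed)
}

new_class_assignment <- function(labels, consensus, provenance,
                                 immune_score = NULL, stroma_score = NULL) {
  structure(list(labels = labels, consensus = consensus,
                 provenance = provenance,
                 immune_score = immune_score, stroma_score = stroma_score),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("class_assignment (%s): %d samples\n", x$provenance, length(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Label a two-cluster partition as immune vs non-immune
#'
#' The cluster with the higher mean immune enrichment score becomes the
#' immune class; labelling is invariant to how the clusters are numbered.
#'
#' @param clustering result of [consensus_cluster()] (or any named
#'   2-level integer partition, in which case `consensus` may be `NULL`).
#' @param immune_scores numeric vector named by sample.
#' @return a `class_assignment` with labels in `{"immune", "non_immune"}`.
#' @export
assign_immune_class <- function(clustering, immune_scores) {
  part <- if (is.list(clustering)) clustering$partition else clustering
  cons <- if (is.list(clustering)) clustering$consensus else NULL
  lev <- sort(unique(part))
  if (length(lev) != 2) abort("partition must contain exactly 2 non-empty clusters")
  if (!all(names(part) %in% names(immune_scores)))
    abort("immune_scores does not cover all samples")
  sc <- immune_scores[names(part)]
  means <- tapply(sc, part, mean)
  if (abs(diff(means)) < 1e-9)
    abort("ambiguous assignment: cluster mean immune scores are equal")
  immune_cluster <- lev[which.max(means[as.character(lev)])]
  labels <- ifelse(part == immune_cluster, "immune", "non_immune")
  names(labels) <- names(part)
  new_class_assignment(labels, cons, "discovered", immune_score = sc)
}

# exact 1-D 2-means: threshold split of sorted values minimizing within-SS;
# deterministic (first minimizing split), shift-invariant
split_1d_kmeans <- function(x) {
  ord <- order(x, names(x), method = "radix")
  v <- x[ord]
  n <- length(v)
  css <- cumsum(v); css2 <- cumsum(v^2)
  wss <- vapply(seq_len(n - 1), function(i) {
    s1 <- css[i]; s2 <- css[n] - s1
    (css2[i] - s1^2 / i) + (css2[n] - css2[i] - s2^2 / (n - i))
  }, numeric(1))
  cut <- which.min(wss)
  grp <- integer(n); grp[ord] <- rep(1:2, c(cut, n - cut))
  names(grp) <- names(x)
  grp  # group 2 has the larger values
}

#' Split the immune class into active-immune and exhausted subtypes
#'
#' Within the immune class, samples are split by a one-dimensional 2-means
#' on the activated-stroma enrichment score (solved exactly over sorted
#' split points, hence deterministic and shift-invariant). The
#' higher-stroma cluster is the exhausted subtype: activated stroma marks
#' the TGF-beta-driven, wound-healing microenvironment in which effector
#' function collapses; the remainder is active-immune.
#'
#' @param assignment a `class_assignment` with immune/non_immune labels.
#' @param stroma_scores activated-stroma enrichment scores named by sample.
#' @return the assignment with labels in
#'   `{"active_immune", "exhausted", "non_immune"}`, stroma scores attached
#'   and the split threshold in `stroma_threshold`.
#' @export
split_immune_subtypes <- function(assignment, stroma_scores) {
  labels <- assignment$labels
  imm <- names(labels)[labels == "immune"]
  if (length(imm) == 0) abort("immune class is empty")
  if (length(imm) < 4) abort("immune class too small to split (< 4 samples)")
  if (!all(imm %in% names(stroma_scores)))
    abort("stroma_scores does not cover the immune-class samples")
  sc <- stroma_scores[imm]
  if (max(sc) - min(sc) < 1e-12) abort("stroma scores are constant; no split exists")
  grp <- split_1d_kmeans(sc)
  labels[imm] <- ifelse(grp[imm] == 2, "exhausted", "active_immune")
  assignment$labels <- labels
  assignment$stroma_score <- sc
  assignment$stroma_threshold <- (max(sc[grp == 1]) + min(sc[grp == 2])) / 2
  assignment
}

#' Build a classification reference for projecting external cohorts
#'
#' Captures everything the discovery cohort learned: exemplar genes, class
#' centroids of per-sample rank-normalized exemplar expression, the basis
#' matrix for the NNLS mode, and the stroma-score split threshold.
#'
#' @param expr discovery gene-by-sample matrix.
#' @param assignment 3-label `class_assignment` from
#'   [split_immune_subtypes()].
#' @param exemplars data.frame from [exemplar_genes()].
#' @param model the `factor_model` (with `immune_factor` set).
#' @param stroma_set character vector: the activated-stroma gene set.
#' @param alpha ssGSEA exponent used for stroma scores.
#' @return object of class `class_reference`.
#' @export
build_reference <- function(expr, assignment, exemplars, model, stroma_set,
                            alpha = 0.25) {
  genes <- exemplars$gene
  labels <- assignment$labels[colnames(expr)]
  # ranks over the full transcriptome, then restricted to exemplar genes:
  # keeps the level information (immune samples rank exemplar genes high)
  rk <- rank_normalize(expr)[genes, , drop = FALSE]
  is_imm <- labels %in% c("active_immune", "exhausted", "immune")
  centroids <- cbind(immune = rowMeans(rk[, is_imm, drop = FALSE]),
                     non_immune = rowMeans(rk[, !is_imm, drop = FALSE]))
  rownames(centroids) <- genes
  # immune-factor relative weight cutoff for the NNLS mode: midpoint of
  # class means of H[immune, ]/colSums(H)
  rel <- model$H[model$immune_factor, ] / pmax(colSums(model$H), 1e-12)
  nnls_threshold <- (mean(rel[is_imm]) + mean(rel[!is_imm])) / 2
  structure(list(exemplar_genes = genes, centroids = centroids,
                 W = model$W, immune_factor = model$immune_factor,
                 nnls_threshold = nnls_threshold,
                 stroma_set = stroma_set, alpha = alpha,
                 stroma_threshold = assignment$stroma_threshold),
            class = "class_reference")
}

#' Project a new cohort onto a discovered immune classification
#'
#' Assigns immune vs non-immune on the shared exemplar genes, either by
#' nearest centroid (default): each new sample's expression is converted to
#' per-sample ranks over its full transcriptome, restricted to the shared
#' exemplar genes, and assigned to the closer (Euclidean) of the discovery
#' class centroids in the same rank space — or by non-negative
#' least-squares regression of each sample onto the discovery basis `W`
#' followed by thresholding the immune factor's relative weight.
#' Transcriptome-wide ranks keep the level signal (immune samples rank the
#' exemplar genes uniformly high) while staying platform-robust.
#' Projected immune samples are then split into
#' active-immune vs exhausted by their activated-stroma enrichment score
#' against the discovery split threshold.
#'
#' @param reference a `class_reference` from [build_reference()].
#' @param new_expr gene-by-sample matrix of the external cohort.
#' @param mode `"centroid"` (default) or `"nnls"`.
#' @return a `class_assignment` with `provenance = "projected"`.
#' @export
project_cohort <- function(reference, new_expr, mode = c("centroid", "nnls")) {
  assert_matrix(new_expr, "new_expr")
  mode <- match.arg(mode)
  if (ncol(new_expr) == 0) abort("empty cohort")
  shared <- intersect(reference$exemplar_genes, rownames(new_expr))
  missing <- setdiff(reference$exemplar_genes, rownames(new_expr))
  if (length(shared) < 0.5 * length(reference$exemplar_genes))
    abort("only %d/%d exemplar genes present in new cohort; missing: %s",
          length(shared), length(reference$exemplar_genes),
          paste(utils::head(missing, 10), collapse = ", "))
  if (mode == "centroid") {
    rk <- rank_normalize(new_expr)[shared, , drop = FALSE]
    cen <- reference$centroids[shared, , drop = FALSE]
    d2 <- vapply(colnames(cen),
                 function(cl) colSums((rk - cen[, cl])^2), numeric(ncol(rk)))
    if (is.null(dim(d2))) d2 <- matrix(d2, 1, dimnames = list(NULL, colnames(cen)))
    labels <- colnames(d2)[max.col(-d2, ties.method = "first")]
  } else {
    wshare <- intersect(rownames(reference$W), rownames(new_expr))
    w <- reference$W[wshare, , drop = FALSE]
    rel <- apply(new_expr[wshare, , drop = FALSE], 2, function(x) {
      h <- pracma::lsqnonneg(w, x)$x
      h[reference$immune_factor] / max(sum(h), 1e-12)
    })
    labels <- ifelse(rel > reference$nnls_threshold, "immune", "non_immune")
  }
  names(labels) <- colnames(new_expr)
  imm <- names(labels)[labels == "immune"]
  stroma <- NULL
  if (length(imm) > 0) {
    shared_str <- intersect(reference$stroma_set, rownames(new_expr))
    if (length(shared_str) == 0) abort("no activated-stroma genes in new cohort")
    stroma <- ssgsea_scores(new_expr, list(stroma = reference$stroma_set),
                            alpha = reference$alpha)[1, ]
    labels[imm] <- ifelse(stroma[imm] > reference$stroma_threshold,
                          "exhausted", "active_immune")
  }
  new_class_assignment(labels, NULL, "projected", stroma_score = stroma)
}
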