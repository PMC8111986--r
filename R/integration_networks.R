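# miRNA-target / lncRNA-miRNA-mRNA network assembly and multi-omics
# integration rules. All operations are pure set/join algebra: outputs are
# permutation-invariant and exactly reproducible.

#' Database-supported targets of differential miRNAs
#'
#' Keeps (miRNA, gene) links for the supplied differentially expressed
#' functional miRNAs (DEFMs). Under the default `"both"` rule a link must be
#' experimentally validated AND computationally predicted by both prediction
#' databases; `"either"` requires validation plus prediction in at least one
#' database. Targets are annotated with whether they are differentially
#' expressed genes and in which direction.
#'
#' @param defms data.frame with at least `feature` (miRNA id); typically a
#'   [differential_expression()] table filtered to passing miRNAs.
#' @param validated data.frame `mirna`, `gene` of validated interactions.
#' @param predicted data.frame `mirna`, `gene`, `db` of predicted
#'   interactions from (at least) two databases.
#' @param rule `"both"` or `"either"`.
#' @param degs optional DE table for the mRNA layer (`feature`, `pass`,
#'   `direction`).
#' @return data.frame `mirna`, `gene`, `is_deg`, `deg_direction`, with the
#'   rule recorded in the `"rule"` attribute.
#' @export
mirna_target_links <- function(defms, validated, predicted,
                               rule = c("both", "either"), degs = NULL) {
  rule <- match.arg(rule)
  if (nrow(defms) == 0) abort("no differential miRNAs supplied")
  key <- function(d) paste(d$mirna, d$gene, sep = "\r")
  val <- validated[validated$mirna %in% defms$feature, c("mirna", "gene")]
  val <- unique(val)
  pred <- predicted[predicted$mirna %in% defms$feature, ]
  dbs <- sort(unique(predicted$db))
  n_db <- tapply(pred$db, key(pred), function(x) length(unique(x)))
  need <- if (rule == "both") length(dbs) else 1L
  keep <- val[key(val) %in% names(n_db)[n_db >= need], , drop = FALSE]
  keep <- keep[order(keep$mirna, keep$gene), , drop = FALSE]
  if (is.null(degs)) {
    keep$is_deg <- NA
    keep$deg_direction <- NA_character_
  } else {
    pasg <- degs[degs$pass, ]
    keep$is_deg <- keep$gene %in% pasg$feature
    keep$deg_direction <- pasg$direction[match(keep$gene, pasg$feature)]
  }
  rownames(keep) <- NULL
  attr(keep, "rule") <- rule
  keep
}

#' lncRNA - miRNA - mRNA tripartite network
#'
#' Restricts lncRNA-to-miRNA edges to the differential lncRNAs, then joins
#' miRNA-to-gene edges for the miRNAs reached in the first step; genes are
#' annotated as DEG or not. Degree-0 miRNAs (no gene edges) keep their
#' lncRNA edge.
#'
#' @param diff_lncrnas character vector of differential lncRNA ids.
#' @param lnc_mir_edges data.frame `lncrna`, `mirna`.
#' @param mir_gene_edges data.frame `mirna`, `gene`.
#' @param degs character vector of differentially expressed gene ids.
#' @return list with `lnc_mir` and `mir_gene` edge data.frames (the latter
#'   with `is_deg`), `mir_degree` (genes per retained miRNA) and
#'   `n_components` of the combined graph.
#' @export
lncrna_network <- function(diff_lncrnas, lnc_mir_edges, mir_gene_edges, degs) {
  if (nrow(lnc_mir_edges) == 0 || nrow(mir_gene_edges) == 0)
    abort("edge tables must be non-empty")
  e1 <- unique(lnc_mir_edges[lnc_mir_edges$lncrna %in% diff_lncrnas,
                             c("lncrna", "mirna")])
  e2 <- unique(mir_gene_edges[mir_gene_edges$mirna %in% e1$mirna,
                              c("mirna", "gene")])
  e2$is_deg <- e2$gene %in% degs
  e1 <- e1[order(e1$lncrna, e1$mirna), , drop = FALSE]
  e2 <- e2[order(e2$mirna, e2$gene), , drop = FALSE]
  rownames(e1) <- rownames(e2) <- NULL
  deg <- table(factor(e2$mirna, levels = sort(unique(e1$mirna))))
  # connected components via union-find over the combined bipartite edges
  nodes <- unique(c(paste0("L:", e1$lncrna), paste0("M:", e1$mirna),
                    paste0("M:", e2$mirna), paste0("G:", e2$gene)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  link <- function(a, b) {
    ra <- find(match(a, nodes)); rb <- find(match(b, nodes))
    if (ra != rb) parent[[ra]] <<- rb
  }
  for (i in seq_len(nrow(e1))) link(paste0("L:", e1$lncrna[i]), paste0("M:", e1$mirna[i]))
  for (i in seq_len(nrow(e2))) link(paste0("M:", e2$mirna[i]), paste0("G:", e2$gene[i]))
  roots <- vapply(seq_along(nodes), find, numeric(1))
  list(lnc_mir = e1, mir_gene = e2,
       mir_degree = as.data.frame(deg, responseName = "n_genes",
                                  stringsAsFactors = FALSE),
       n_components = length(unique(roots)))
}

#' Multi-omics integrated gene set ("at least m of n layers")
#'
#' @param hits named list of character vectors, one per omics layer (e.g.
#'   DEG, CNV, SNP, miRNA-target ...); names must be unique.
#' @param min_layers minimum number of layers a gene must appear in
#'   (default 2). `min_layers = 1` is the union, `min_layers =
#'   length(hits)` the intersection.
#' @return list with `genes` (sorted character vector) and `membership`
#'   (logical gene-by-layer matrix over the union, plus an `n_layers`
#'   column attribute via rowSums).
#' @export
multiomics_venn <- function(hits, min_layers = 2) {
  if (length(hits) < 2) abort("need >= 2 layers")
  if (anyDuplicated(names(hits)) || is.null(names(hits)))
    abort("layers must be uniquely named")
  if (min_layers > length(hits)) abort("min_layers exceeds the number of layers")
  universe <- sort(unique(unlist(hits)))
  memb <- vapply(hits, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, 1, dimnames = list(universe, names(hits)))
  rownames(memb) <- universe
  n <- rowSums(memb)
  list(genes = universe[n >= min_layers], membership = memb, n_layers = n)
}

#' Hypergeometric pathway over-representation test
#'
#' One-sided hypergeometric tail per pathway (probability of an overlap at
#' least as large as observed, given the list and universe sizes), with BH
#' adjustment across pathways. Pathways with no gene in the universe are
#' skipped.
#'
#' @param gene_list character vector (must be a subset of `universe`).
#' @param universe character vector of all assayed genes.
#' @param pathways named list of gene sets.
#' @return data.frame `pathway`, `overlap`, `pathway_size`, `p`, `q`, plus
#'   overlapping genes (comma-separated).
#' @export
overrepresentation_test <- function(gene_list, universe, pathways) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe)) abort("gene_list must be a subset of the universe")
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    if (length(pw) == 0) return(NULL)
    ov <- intersect(gene_list, pw)
    p <- stats::phyper(length(ov) - 1, length(pw), length(universe) - length(pw),
                       length(gene_list), lower.tail = FALSE)
    data.frame(pathway = nm, overlap = length(ov), pathway_size = length(pw),
               p = p, genes = paste(sort(ov), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) abort("no pathway overlaps the universe")
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out[, c("pathway", "overlap", "pathway_size", "p", "q", "genes")]
}

#' Bipartite pathway-gene network from enrichment results
#'
#' @param enrichment [overrepresentation_test()] table, typically filtered
#'   to significant pathways.
#' @param gene_list the gene list used for enrichment.
#' @param pathways the pathway collection.
#' @return list with `edges` (data.frame `pathway`, `gene`) and `nodes`
#'   (ids, type, p-value for pathway nodes).
#' @export
pathway_gene_network <- function(enrichment, gene_list, pathways) {
  edges <- do.call(rbind, lapply(enrichment$pathway, function(nm) {
    genes <- sort(intersect(gene_list, pathways[[nm]]))
    if (length(genes) == 0) return(NULL)
    data.frame(pathway = nm, gene = genes)
  }))
  if (is.null(edges)) edges <- data.frame(pathway = character(0), gene = character(0))
  nodes <- rbind(
    data.frame(id = enrichment$pathway, type = "pathway", p = enrichment$p),
    data.frame(id = sort(unique(edges$gene)), type = "gene", p = NA_real_))
  list(edges = edges, nodes = nodes)
}
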