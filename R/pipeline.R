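# End-to-end orchestration: discovery wrapper, config-driven pipeline with
# manifest, and class-proportion reporting.

#' Discover the immune classification of a cohort
#'
#' Runs the full discovery chain on a non-negative gene-by-sample
#' expression matrix: (1) ssGSEA immune and activated-stroma scores;
#' (2) MAD pre-filter and KL-NMF virtual microdissection at `k` factors;
#' (3) identification of the immune factor by correlation with the immune
#' score; (4) exemplar-gene extraction; (5) consensus clustering of samples
#' on the exemplar genes into immune vs non-immune; (6) split of the immune
#' class into active-immune vs exhausted on the stroma score. Returns the
#' assignment together with a projection reference for external cohorts.
#'
#' @param expr non-negative gene-by-sample matrix.
#' @param immune_sets named list of immune gene sets; their mean ssGSEA
#'   score is the immune enrichment score.
#' @param stroma_set character vector: activated-stroma gene set.
#' @param k NMF rank (default 3: immune, stroma, tumour compartments).
#' @param n_var_genes MAD filter size (default 1500).
#' @param n_restarts,max_iter NMF controls.
#' @param m,min_ratio exemplar-gene controls (see [exemplar_genes()]).
#' @param n_resamples,sample_fraction consensus-clustering controls.
#' @param alpha ssGSEA exponent.
#' @param seed integer seed governing all randomized stages.
#' @return list: `assignment` (3-label `class_assignment`), `model`,
#'   `exemplars`, `scores` (immune/stroma per sample), `reference`
#'   (`class_reference`), `consensus`.
#' @export
discover_immune_classes <- function(expr, immune_sets, stroma_set,
                                    k = 3, n_var_genes = 1500,
                                    n_restarts = 5, max_iter = 500,
                                    m = 150, min_ratio = 2,
                                    n_resamples = 100, sample_fraction = 0.8,
                                    alpha = 0.25, seed = 1) {
  sets <- c(immune_sets, list(.stroma = stroma_set))
  es <- ssgsea_scores(expr, sets, alpha = alpha)
  immune_score <- colMeans(es[names(immune_sets), , drop = FALSE])
  stroma_score <- es[".stroma", ]
  sub <- filter_variable_genes(expr, n_var_genes)
  model <- nmf(sub, k, n_restarts = n_restarts, max_iter = max_iter, seed = seed)
  model <- identify_immune_factor(model, immune_score)
  exemplars <- exemplar_genes(model, m = m, min_ratio = min_ratio)
  rk <- rank_normalize(expr)
  cons <- consensus_cluster(rk[exemplars$gene, , drop = FALSE],
                            k_clusters = 2, n_resamples = n_resamples,
                            sample_fraction = sample_fraction,
                            seed = derive_seed(seed, 2))
  assignment <- assign_immune_class(cons, immune_score)
  assignment <- split_immune_subtypes(assignment, stroma_score)
  reference <- build_reference(expr, assignment, exemplars, model, stroma_set,
                               alpha = alpha)
  list(assignment = assignment, model = model, exemplars = exemplars,
       scores = data.frame(sample = colnames(expr), immune = immune_score,
                           stroma = stroma_score, row.names = NULL),
       reference = reference, consensus = cons)
}

#' Per-class counts and percentages
#'
#' @param assignment a `class_assignment` (or a label vector).
#' @return data.frame `class`, `count`, `percent` (percent of the total,
#'   rounded half-up to 2 decimals).
#' @export
class_proportions <- function(assignment) {
  labels <- if (inherits(assignment, "class_assignment")) assignment$labels else assignment
  if (length(labels) == 0) abort("empty assignment")
  tab <- table(labels)
  data.frame(class = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / length(labels), 2),
             row.names = NULL)
}

stage_output <- function(dir, name, obj) {
  path <- file.path(dir, paste0(name, ".tsv"))
  if (is.matrix(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path
}

#' Run the full analysis pipeline on a synthetic or user-supplied cohort
#'
#' Executes the stages in dependency order — enrichment scoring,
#' factorization, classification, subtype split, self-projection,
#' differential expression per layer, genomic scores, mutational
#' signatures, multi-omics integration and cohort statistics — writing one
#' TSV per stage plus a JSON manifest listing every output with the
#' parameters and seed that produced it. A stage failure stops the run
#' with the stage name in the error; outputs of completed stages remain on
#' disk.
#'
#' @param config named list (or path to a YAML file with the same fields):
#'   `out_dir` (required), `seed` (default 1), `cohort` (a
#'   `synthetic_cohort`; when absent one is generated from
#'   `cohort_params`), `cohort_params` (arguments to [cohort_config()]),
#'   and optional overrides `k`, `n_var_genes`, `m`, `min_ratio`,
#'   `n_resamples`, `fdr`, `lfc`, `n_signatures`.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config[["out_dir"]])) abort("config$out_dir is required")
  seed <- config[["seed"]] %||% 1
  dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, params, paths) {
    manifest$stages[[stage]] <<- list(params = params, outputs = paths)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e)
      abort("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  cohort <- config[["cohort"]]
  if (is.null(cohort)) {
    params <- config[["cohort_params"]] %||% list()
    params$seed <- params$seed %||% seed
    cohort <- run_stage("simulate", function()
      generate_cohort(do.call(cohort_config, params)))
    note("simulate", params, character(0))
  }
  expr <- cohort$expression
  sets <- cohort$gene_sets
  immune_sets <- sets[setdiff(names(sets), "activated_stroma")]
  stroma_set <- sets$activated_stroma

  disc <- run_stage("classify", function()
    discover_immune_classes(expr, immune_sets, stroma_set,
                            k = config[["k"]] %||% 3,
                            n_var_genes = config[["n_var_genes"]] %||% 1500,
                            m = config[["m"]] %||% 150,
                            min_ratio = config[["min_ratio"]] %||% 2,
                            n_resamples = config[["n_resamples"]] %||% 100,
                            seed = seed))
  labels <- disc$assignment$labels
  lab_tab <- data.frame(sample = names(labels), class = unname(labels),
                        immune_score = disc$scores$immune,
                        stroma_score = disc$scores$stroma,
                        provenance = disc$assignment$provenance)
  p1 <- stage_output(config[["out_dir"]], "class_labels", lab_tab)
  p2 <- stage_output(config[["out_dir"]], "class_proportions", class_proportions(disc$assignment))
  p3 <- stage_output(config[["out_dir"]], "consensus_matrix", disc$consensus$consensus)
  p4 <- stage_output(config[["out_dir"]], "exemplar_genes", disc$exemplars)
  note("classify", list(k = config[["k"]] %||% 3, m = config[["m"]] %||% 150,
                        n_resamples = config[["n_resamples"]] %||% 100, seed = seed),
       c(p1, p2, p3, p4))

  proj <- run_stage("project", function()
    project_cohort(disc$reference, expr))
  agree <- mean(proj$labels == labels)
  p5 <- stage_output(config[["out_dir"]], "projection",
                     data.frame(sample = names(proj$labels),
                                class = unname(proj$labels),
                                provenance = proj$provenance))
  note("project", list(mode = "centroid", self_agreement = agree), p5)

  grp2 <- ifelse(labels %in% c("active_immune", "exhausted"), "immune", "non_immune")
  fdr <- config[["fdr"]] %||% 0.05; lfc <- config[["lfc"]] %||% 1.0
  de <- run_stage("de", function() list(
    mrna = differential_expression(expr, grp2, fdr = fdr, lfc = lfc),
    mirna = differential_expression(cohort$mirna, grp2, fdr = fdr, lfc = 0),
    lncrna = differential_expression(cohort$lncrna, grp2, fdr = fdr, lfc = 0),
    protein = differential_expression(cohort$protein, grp2, fdr = fdr, lfc = 0)))
  pde <- vapply(names(de), function(nm)
    stage_output(config[["out_dir"]], paste0("de_", nm), de[[nm]]), character(1))
  note("de", list(fdr = fdr, lfc = lfc, test = "welch_t"), pde)

  gsea <- run_stage("gsea", function() {
    ranked <- stats::setNames(de$mrna$logFC, de$mrna$feature)
    preranked_gsea(ranked, sets, n_perm = config[["n_perm"]] %||% 200,
                   seed = derive_seed(seed, 3))
  })
  p6 <- stage_output(config[["out_dir"]], "gsea", gsea)
  note("gsea", list(n_perm = config[["n_perm"]] %||% 200), p6)

  genom <- run_stage("genomics", function() {
    fga <- fraction_genome_altered(cohort$segments)
    an <- aneuploidy_score(cohort$segments)
    merge(fga, an, by = "sample")
  })
  p7 <- stage_output(config[["out_dir"]], "genomic_scores", genom)
  note("genomics", list(burden_thr = 0.1, arm_thr = 0.1), p7)

  mutsig <- run_stage("mutsig", function() {
    counts <- context_count_matrix(cohort$mutations,
                                   samples = colnames(expr))
    extract_mutational_signatures(counts, k = config[["n_signatures"]] %||% 3,
                                  seed = derive_seed(seed, 4))
  })
  p8 <- stage_output(config[["out_dir"]], "mutational_signatures", mutsig$signatures)
  p9 <- stage_output(config[["out_dir"]], "signature_match", mutsig$match)
  note("mutsig", list(k = config[["n_signatures"]] %||% 3), c(p8, p9))

  integ <- run_stage("integrate", function() {
    freq_genes <- mutation_frequency_filter(cohort$mutations, ncol(expr))
    hits <- list(DEG = de$mrna$feature[de$mrna$pass],
                 miRNA = de$mirna$feature[de$mirna$pass],
                 lncRNA = de$lncrna$feature[de$lncrna$pass],
                 SNP = freq_genes)
    multiomics_venn(hits, min_layers = config[["min_layers"]] %||% 2)
  })
  p10 <- stage_output(config[["out_dir"]], "integrated_genes",
                      data.frame(gene = integ$genes))
  note("integrate", list(min_layers = config[["min_layers"]] %||% 2), p10)

  stats_out <- run_stage("stats", function() {
    cl <- cohort$clinical
    tab <- table(cl$hpv_state, cl$class)
    chi <- chi_square_test(unclass(tab))
    lr <- logrank_test(cl$time, cl$event, cl$class)
    data.frame(test = c("hpv_by_class_chisq", "logrank_3class"),
               statistic = c(chi$statistic, lr$statistic),
               df = c(chi$df, lr$df), p = c(chi$p, lr$p))
  })
  p11 <- stage_output(config[["out_dir"]], "cohort_stats", stats_out)
  note("stats", list(), p11)

  jsonlite::write_json(manifest, file.path(config[["out_dir"]], "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
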