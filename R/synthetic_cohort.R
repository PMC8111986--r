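# Synthetic cohorts with planted immune / activated-stroma / tumour factors,
# class-linked clinical covariates, survival, copy-number segments and
# mutation catalogues. Every downstream stage of the package is exercised
# against the planted truth.

CLASSES <- c("active", "exhausted", "non_immune")

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the training cohort the classification was designed
#' for: 293 samples whose class proportions follow the printed class sizes
#' (153 active-immune, 74 exhausted, 64 non-immune), three expression
#' compartments (immune, activated stroma, tumour), exhausted samples
#' loading on both immune and stroma factors, class-linked clinical
#' covariates with explicit "Unknown" levels, exponential survival with a
#' worse hazard in the exhausted subtype, class-specific copy-number
#' alteration profiles (highest fraction altered in exhausted, most
#' segments in non-immune) and mutation catalogues drawn from known
#' mixtures of the packaged reference signatures.
#'
#' @param n_samples cohort size.
#' @param n_genes expression genes (>= 500; the first 300 form the planted
#'   immune/stroma/tumour blocks).
#' @param k_factors number of planted factors; the generator plants exactly
#'   3 compartments, so values other than 3 are rejected (>= 2 is the
#'   formal lower bound).
#' @param class_proportions named simplex over
#'   `c("active","exhausted","non_immune")`.
#' @param factor_loading_scale positive multiplier on planted basis weights.
#' @param noise_sd sd of the truncated Gaussian expression noise (0 gives
#'   exactly `W_true %*% H_true` when `module_sd` is also 0).
#' @param module_sd sd (log scale) of mean-one lognormal per-sample
#'   modulation of the planted immune submodules and the stroma block;
#'   emulates the modular substructure of real infiltrates (different
#'   immune-cell compartments varying semi-independently), without which
#'   exemplar-gene expression is exactly rank-1 and sample-sample
#'   correlations are degenerate. Set 0 to disable.
#' @param hazard_ratios per-class hazards relative to active-immune.
#' @param seg_profile per-class expected fraction of the genome altered.
#' @param signature_mixtures class-by-reference-signature simplex matrix.
#' @param mutation_rate per-class mean mutation count (Poisson).
#' @param baseline_median_survival median survival (days) of the reference
#'   class.
#' @param censor_max upper bound of the independent uniform censoring time.
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 293,
                          n_genes = 2000,
                          k_factors = 3,
                          class_proportions = c(active = 153, exhausted = 74,
                                                non_immune = 64) / 291,
                          factor_loading_scale = 1,
                          noise_sd = 0.15,
                          module_sd = 0.4,
                          hazard_ratios = c(active = 1, exhausted = 2.2,
                                            non_immune = 1.4),
                          seg_profile = c(active = 0.12, exhausted = 0.30,
                                          non_immune = 0.20),
                          signature_mixtures = default_signature_mixtures(),
                          mutation_rate = c(active = 60, exhausted = 150,
                                            non_immune = 100),
                          baseline_median_survival = 2500,
                          censor_max = 5000,
                          seed = 1) {
  if (k_factors < 2) abort("k_factors must be >= 2")
  if (k_factors != 3) abort("the generator plants exactly 3 compartments (k_factors = 3)")
  if (n_genes < 500) abort("n_genes must be >= 500")
  if (!setequal(names(class_proportions), CLASSES))
    abort("class_proportions must be named over %s", paste(CLASSES, collapse = ", "))
  class_proportions <- class_proportions[CLASSES]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    abort("class_proportions must sum to 1")
  if (any(class_proportions < 0)) abort("class_proportions must be non-negative")
  if (factor_loading_scale <= 0) abort("factor_loading_scale must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (module_sd < 0) abort("module_sd must be >= 0")
  if (any(hazard_ratios <= 0)) abort("hazard_ratios must be positive")
  if (any(seg_profile < 0 | seg_profile > 1)) abort("seg_profile must lie in [0, 1]")
  if (any(abs(rowSums(signature_mixtures) - 1) > 1e-9))
    abort("signature_mixtures rows must sum to 1")
  structure(list(n_samples = n_samples, n_genes = n_genes, k_factors = k_factors,
                 class_proportions = class_proportions,
                 factor_loading_scale = factor_loading_scale,
                 noise_sd = noise_sd, module_sd = module_sd,
                 hazard_ratios = hazard_ratios[CLASSES],
                 seg_profile = seg_profile[CLASSES],
                 signature_mixtures = signature_mixtures,
                 mutation_rate = mutation_rate[CLASSES],
                 baseline_median_survival = baseline_median_survival,
                 censor_max = censor_max, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_signature_mixtures <- function() {
  m <- rbind(active = c(0.65, 0.25, 0.10, 0.00, 0.00),
             exhausted = c(0.15, 0.15, 0.60, 0.10, 0.00),
             non_immune = c(0.10, 0.10, 0.10, 0.10, 0.60))
  colnames(m) <- colnames(reference_signatures())
  m
}

# planted gene blocks and the packaged gene-set collection over them
planted_genes <- function(n_genes) {
  imm <- sprintf("IMM%03d", 1:120)
  str <- sprintf("STR%03d", 1:80)
  tum <- sprintf("TUM%03d", 1:100)
  bg <- sprintf("BG%04d", seq_len(n_genes - 300))
  list(immune = imm, stroma = str, tumour = tum, background = bg,
       all = c(imm, str, tum, bg),
       sets = list(immune_signature = imm[1:60],
                   CD8_T_cells = imm[61:75],
                   B_cells = imm[76:90],
                   Macrophages = imm[91:105],
                   type_I_IFN = imm[106:120],
                   activated_stroma = str[1:50]))
}

# Table 1-style class-conditional clinical sampling probabilities
clinical_probs <- function() {
  list(
    hpv_state = list(levels = c("Positive", "Negative"),
                     active = c(147, 6) / 153, exhausted = c(70, 4) / 74,
                     non_immune = c(53, 11) / 64),
    smoke = list(levels = c("Yes", "No", "Unknown"),
                 active = c(32, 101, 20) / 153, exhausted = c(19, 46, 9) / 74,
                 non_immune = c(12, 45, 7) / 64),
    clinical_stage = list(levels = c("I", "II", "III", "IV", "Unknown"),
                          active = c(84, 35, 23, 7, 4) / 153,
                          exhausted = c(32, 18, 13, 9, 2) / 74,
                          non_immune = c(43, 11, 5, 5, 0) / 64),
    radiation = list(levels = c("Yes", "No", "Unknown"),
                     active = c(77, 31, 45) / 153, exhausted = c(35, 13, 26) / 74,
                     non_immune = c(31, 12, 21) / 64),
    histology = list(levels = c("Squamous", "Adenosquamous", "Adenocarcinoma"),
                     active = c(150, 0, 3) / 153, exhausted = c(73, 1, 0) / 74,
                     non_immune = c(18, 3, 43) / 64))
}

#' Simulate a mutation catalogue from signature exposures
#'
#' Draws each sample's 96-context counts from a multinomial whose
#' probability vector is the exposure-weighted mixture of reference
#' signature profiles, then expands the counts into minimal MAF records
#' with a `context96` column.
#'
#' @param exposures reference-signature-by-sample matrix of non-negative
#'   exposures; each column must sum to 1 (a simplex).
#' @param n_mutations per-sample mutation count (scalar or vector).
#' @param reference 96-by-k column-stochastic signature matrix.
#' @param seed integer seed.
#' @param gene_pool genes to attribute mutations to (uniform; default 200
#'   invented symbols).
#' @return data.frame with MAF-minimal columns (`Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#'   `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`,
#'   `context96`). `n_mutations = 0` for all samples gives an empty
#'   catalogue.
#' @export
generate_mutation_catalog <- function(exposures, n_mutations,
                                      reference = reference_signatures(),
                                      seed = 1, gene_pool = sprintf("GENE%03d", 1:200)) {
  if (is.null(dim(exposures))) exposures <- matrix(exposures, ncol = 1,
                                                   dimnames = list(NULL, "S1"))
  if (any(exposures < 0) || any(abs(colSums(exposures) - 1) > 1e-9))
    abort("exposures columns must be non-negative and sum to 1")
  if (nrow(exposures) != ncol(reference))
    abort("exposures rows must match reference signature count")
  set.seed(seed)
  ctx <- rownames(reference)
  n_mutations <- rep(n_mutations, length.out = ncol(exposures))
  recs <- vector("list", ncol(exposures))
  for (s in seq_len(ncol(exposures))) {
    n <- n_mutations[[s]]
    if (n == 0) next
    p <- as.vector(reference %*% exposures[, s])
    counts <- stats::rmultinom(1, n, p)[, 1]
    codes <- rep(ctx, counts)
    ref_base <- substr(codes, 3, 3)
    alt_base <- substr(codes, 5, 5)
    recs[[s]] <- data.frame(
      Hugo_Symbol = sample(gene_pool, n, replace = TRUE),
      Tumor_Sample_Barcode = colnames(exposures)[s],
      Chromosome = as.character(sample(1:22, n, replace = TRUE)),
      Start_Position = sample.int(1e8, n),
      Reference_Allele = ref_base,
      Tumor_Seq_Allele2 = alt_base,
      Variant_Classification = sample(c("Missense_Mutation", "Silent",
                                        "Nonsense_Mutation"), n,
                                      replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      context96 = codes)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0)
    return(data.frame(Hugo_Symbol = character(0), Tumor_Sample_Barcode = character(0),
                      Chromosome = character(0), Start_Position = integer(0),
                      Reference_Allele = character(0), Tumor_Seq_Allele2 = character(0),
                      Variant_Classification = character(0), context96 = character(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# per-sample copy-number segments over the packaged arm table
simulate_segments <- function(samples, classes, seg_profile, arms) {
  seg_lambda <- c(active = 0.4, exhausted = 0.6, non_immune = 1.8)
  recs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    cl <- classes[[i]]
    rows <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      nseg <- 1L + stats::rpois(1, seg_lambda[[cl]])
      bounds <- sort(c(arms$start[a] - 1,
                       sample.int(arms$end[a] - arms$start[a] - 1, nseg - 1) + arms$start[a],
                       arms$end[a]))
      bounds <- unique(bounds)
      k <- length(bounds) - 1
      altered <- stats::runif(k) < seg_profile[[cl]]
      mean_val <- ifelse(altered,
                         sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.25, 0.9),
                         stats::rnorm(k, 0, 0.03))
      rows[[a]] <- data.frame(Sample = samples[[i]],
                              Chromosome = arms$chromosome[a],
                              Start = utils::head(bounds, -1) + 1,
                              End = bounds[-1],
                              Num_Probes = pmax(2L, round((bounds[-1] - utils::head(bounds, -1)) / 1e5)),
                              Segment_Mean = round(mean_val, 4))
    }
    recs[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# feature-by-sample Gaussian table with a planted shift in immune samples
simulate_layer <- function(prefix, n_features, n_diff, samples, is_immune, shift = 1.5) {
  feats <- sprintf("%s%03d", prefix, seq_len(n_features))
  mat <- matrix(stats::rnorm(n_features * length(samples)), n_features,
                dimnames = list(feats, samples))
  diff <- feats[seq_len(n_diff)]
  signs <- rep(c(1, -1), length.out = n_diff)
  mat[diff, is_immune] <- mat[diff, is_immune] + signs * shift
  list(mat = mat, differential = diff, signs = signs)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' See [cohort_config()] for what is planted. Running twice with the same
#' config yields identical outputs.
#'
#' @param config a `cohort_config`.
#' @return list of class `synthetic_cohort`:
#' \describe{
#'   \item{expression}{non-negative gene-by-sample matrix
#'     (`W_true %*% H_true` plus truncated Gaussian noise).}
#'   \item{clinical}{data.frame with covariates (Unknown levels included),
#'     `time` (> 0), `event` (0/1) and the true class label.}
#'   \item{segments}{SEG-style copy-number table.}
#'   \item{mutations}{MAF-minimal catalogue with `context96`.}
#'   \item{mirna,lncrna,protein}{feature-by-sample matrices with planted
#'     immune-vs-non-immune differential features.}
#'   \item{edges}{validated / predicted miRNA-target and lncRNA-miRNA
#'     edge tables.}
#'   \item{gene_sets}{the planted gene-set collection (GMT-writable).}
#'   \item{truth}{`CohortTruth`: labels, `W_true`, `H_true`, signature
#'     exposures, per-sample hazards, differential feature lists.}
#' }
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("config must come from cohort_config()")
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  classes <- sample(CLASSES, n, replace = TRUE, prob = config$class_proportions)
  names(classes) <- samples

  g <- planted_genes(config$n_genes)
  n_genes <- config$n_genes
  w <- matrix(stats::runif(n_genes * 3, 0, 0.03), n_genes, 3,
              dimnames = list(g$all, c("immune", "stroma", "tumour")))
  sc <- config$factor_loading_scale
  w[g$immune, "immune"] <- sc * stats::runif(length(g$immune), 0.5, 1.5)
  w[g$stroma, "stroma"] <- sc * stats::runif(length(g$stroma), 0.5, 1.5)
  w[g$tumour, "tumour"] <- sc * stats::runif(length(g$tumour), 0.5, 1.5)

  h <- matrix(0, 3, n, dimnames = list(colnames(w), samples))
  for (i in seq_len(n)) {
    # active loads on the immune factor only, exhausted on immune + stroma,
    # non-immune on the tumour factor only; "off" factors get a small
    # residual background weight
    h[, i] <- switch(classes[[i]],
      active = c(stats::runif(1, 2.5, 3.5), stats::runif(1, 0, 0.1),
                 stats::runif(1, 0.8, 1.2)),
      exhausted = c(stats::runif(1, 2.0, 3.0), stats::runif(1, 2.0, 3.0),
                    stats::runif(1, 0.8, 1.2)),
      non_immune = c(stats::runif(1, 0, 0.1), stats::runif(1, 0, 0.2),
                     stats::runif(1, 2.5, 3.5)))
  }
  expr <- w %*% h
  if (config$module_sd > 0) {
    mods <- c(g$sets[c("immune_signature", "CD8_T_cells", "B_cells",
                       "Macrophages", "type_I_IFN")],
              list(stroma_block = g$stroma))
    for (m in mods) {
      f <- exp(stats::rnorm(n, 0, config$module_sd) - config$module_sd^2 / 2)
      expr[m, ] <- expr[m, ] * rep(f, each = length(m))
    }
  }
  if (config$noise_sd > 0)
    expr <- pmax(expr + stats::rnorm(length(expr), 0, config$noise_sd), 0)

  cp <- clinical_probs()
  draw <- function(var) {
    out <- character(n)
    for (cl in CLASSES) {
      idx <- classes == cl
      out[idx] <- sample(var$levels, sum(idx), replace = TRUE, prob = var[[cl]])
    }
    factor(out, levels = var$levels)
  }
  age_mean <- c(active = 48.9, exhausted = 47.3, non_immune = 47.2)
  bmi_mean <- c(active = 28.5, exhausted = 27.6, non_immune = 26.9)
  rate0 <- log(2) / config$baseline_median_survival
  hazard <- rate0 * config$hazard_ratios[classes]
  t_event <- stats::rexp(n, hazard)
  t_cens <- stats::runif(n, 0, config$censor_max)
  clinical <- data.frame(
    sample = samples,
    class = unname(classes),
    age = round(stats::rnorm(n, age_mean[classes], 13), 1),
    bmi = round(stats::rnorm(n, bmi_mean[classes], 6), 1),
    hpv_state = draw(cp$hpv_state),
    smoke = draw(cp$smoke),
    clinical_stage = draw(cp$clinical_stage),
    radiation = draw(cp$radiation),
    histology = draw(cp$histology),
    time = pmax(pmin(t_event, t_cens), 0.5),
    event = as.integer(t_event <= t_cens))

  arms <- load_arm_table()
  segments <- simulate_segments(samples, classes, config$seg_profile, arms)

  exposures <- t(config$signature_mixtures[classes, , drop = FALSE])
  colnames(exposures) <- samples
  n_mut <- stats::rpois(n, config$mutation_rate[classes])
  mut_pool <- c(sprintf("GENE%03d", 1:200), rep("MUTNI1", 20), rep("MUTEX1", 20))
  mutations <- generate_mutation_catalog(exposures, n_mut,
                                         seed = derive_seed(config$seed, 7),
                                         gene_pool = mut_pool)

  set.seed(derive_seed(config$seed, 11))
  is_immune <- classes %in% c("active", "exhausted")
  mirna <- simulate_layer("MIR", 150, 20, samples, is_immune)
  lncrna <- simulate_layer("LNC", 200, 30, samples, is_immune)
  protein <- simulate_layer("PRT", 100, 15, samples, is_immune)

  mir_ids <- rownames(mirna$mat)
  gene_univ <- g$all[1:500]
  validated <- unique(data.frame(
    mirna = sample(mir_ids, 600, replace = TRUE),
    gene = sample(gene_univ, 600, replace = TRUE)))
  pred1 <- validated[stats::runif(nrow(validated)) < 0.7, ]
  pred2 <- validated[stats::runif(nrow(validated)) < 0.7, ]
  extra <- data.frame(mirna = sample(mir_ids, 200, replace = TRUE),
                      gene = sample(gene_univ, 200, replace = TRUE))
  predicted <- unique(rbind(cbind(pred1, db = "miranda"),
                            cbind(pred2, db = "mirdb"),
                            cbind(extra, db = sample(c("miranda", "mirdb"), 200,
                                                     replace = TRUE))))
  lnc_mir <- unique(data.frame(lncrna = sample(rownames(lncrna$mat), 400, replace = TRUE),
                               mirna = sample(mir_ids, 400, replace = TRUE)))

  truth <- list(labels = classes, W_true = w, H_true = h,
                exposures = exposures, hazards = hazard,
                differential = list(mirna = mirna$differential,
                                    lncrna = lncrna$differential,
                                    protein = protein$differential),
                planted_blocks = g[c("immune", "stroma", "tumour")])
  structure(list(expression = expr, clinical = clinical, segments = segments,
                 mutations = mutations, mirna = mirna$mat, lncrna = lncrna$mat,
                 protein = protein$mat,
                 edges = list(validated = validated, predicted = predicted,
                              lnc_mir = lnc_mir),
                 gene_sets = g$sets, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$config$seed))
  print(table(x$truth$labels))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits expression/clinical/miRNA/lncRNA/protein TSVs, a SEG file, a
#' minimal MAF, the planted gene sets as GMT and the ground truth as JSON
#' (labels, exposures, hazards) plus TSVs for `W_true`/`H_true`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, col.names = NA)
  wt(cohort$expression, "expression.tsv")
  wt(cohort$mirna, "mirna.tsv"); wt(cohort$lncrna, "lncrna.tsv")
  wt(cohort$protein, "protein.tsv")
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(cohort$segments, file.path(dir, "segments.seg"))
  utils::write.table(cohort$mutations, file.path(dir, "mutations.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(list(labels = as.list(cohort$truth$labels),
                            exposures = cohort$truth$exposures,
                            hazards = cohort$truth$hazards),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  wt(cohort$truth$W_true, "W_true.tsv"); wt(cohort$truth$H_true, "H_true.tsv")
  invisible(dir)
}
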