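# Consensus clustering, immune-class labelling, subtype split, projection.

block_matrix <- function(seed = 1) {
  # two well-separated sample blocks over 30 features
  set.seed(seed)
  a <- matrix(stats::rnorm(30 * 12, 5), 30, 12)
  b <- matrix(stats::rnorm(30 * 10, -5), 30, 10)
  x <- cbind(a, b)
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:22))
  x
}

test_that("consensus separates planted blocks with a wide gap", {
  x <- block_matrix()
  cc <- consensus_cluster(x, n_resamples = 50, seed = 2)
  truth <- rep(1:2, c(12, 10))
  within <- cc$consensus[outer(truth, truth, "==") & !diag(22)]
  between <- cc$consensus[outer(truth, truth, "!=")]
  expect_gt(mean(within) - mean(between), 0.8)
  expect_true(isSymmetric(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, 22))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  # partition splits the blocks exactly
  expect_equal(length(unique(cc$partition[1:12])), 1)
  expect_equal(length(unique(cc$partition[13:22])), 1)
})

test_that("full subsampling gives a binary consensus", {
  x <- block_matrix(3)
  cc <- consensus_cluster(x, n_resamples = 10, sample_fraction = 1, seed = 4)
  expect_true(all(cc$consensus %in% c(0, 1)))
})

test_that("sample order does not change the partition (up to relabeling)", {
  x <- block_matrix(5)
  set.seed(6)
  perm <- sample(ncol(x))
  cc1 <- consensus_cluster(x, n_resamples = 40, seed = 7)
  cc2 <- consensus_cluster(x[, perm], n_resamples = 40, seed = 7)
  p1 <- cc1$partition[colnames(x)]
  p2 <- cc2$partition[colnames(x)]
  expect_equal(length(unique(paste(p1, p2))), 2)  # one-to-one label mapping
})

test_that("constant rows are dropped, all-constant is an error", {
  x <- block_matrix(8)
  x[1:3, ] <- 7
  expect_warning(consensus_cluster(x, n_resamples = 5, seed = 1),
                 "constant feature rows")
  xc <- matrix(1, 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  expect_error(consensus_cluster(xc), "constant")
})

test_that("immune labelling follows the higher mean enrichment score", {
  part <- stats::setNames(rep(1:2, each = 5), paste0("s", 1:10))
  sc <- stats::setNames(c(rep(1, 5), rep(10, 5)), paste0("s", 1:10))
  a <- assign_immune_class(part, sc)
  expect_true(all(a$labels[6:10] == "immune") && all(a$labels[1:5] == "non_immune"))
  # swapping cluster ids changes nothing
  a2 <- assign_immune_class(3 - part, sc)
  expect_equal(a$labels, a2$labels)
  # equal means are ambiguous
  expect_error(assign_immune_class(part, stats::setNames(rep(1, 10), names(part))),
               "ambiguous")
})

test_that("discovered immune class matches the planted one (high Rand index)", {
  sd <- small_discovery()
  lab <- sd$disc$assignment$labels
  tr <- truth_labels(sd$cohort)[names(lab)]
  two <- function(v) ifelse(v == "non_immune", "non_immune", "immune")
  a <- two(lab); b <- two(tr)
  n <- length(a)
  agree <- outer(a, a, "==") == outer(b, b, "==")
  rand <- mean(agree[upper.tri(agree)])
  expect_gte(rand, 0.95)
})

test_that("stroma split isolates the high-stroma mode and is shift-invariant", {
  labels <- stats::setNames(c(rep("immune", 20), rep("non_immune", 5)),
                            paste0("s", 1:25))
  asg <- immunoclass:::new_class_assignment(labels, NULL, "discovered")
  set.seed(9)
  sc <- stats::setNames(c(stats::rnorm(12, 0, 0.3), stats::rnorm(8, 6, 0.3),
                          stats::rnorm(5, 3)), paste0("s", 1:25))
  out <- split_immune_subtypes(asg, sc)
  expect_true(all(out$labels[1:12] == "active_immune"))
  expect_true(all(out$labels[13:20] == "exhausted"))
  expect_true(all(out$labels[21:25] == "non_immune"))
  shifted <- split_immune_subtypes(asg, sc + 100)
  expect_equal(out$labels, shifted$labels)
  # degenerate: constant scores
  expect_error(split_immune_subtypes(asg, stats::setNames(rep(2, 25), names(sc))),
               "constant")
  # too small to split
  tiny <- immunoclass:::new_class_assignment(
    stats::setNames(c(rep("immune", 3), "non_immune"), paste0("s", 1:4)),
    NULL, "discovered")
  expect_error(split_immune_subtypes(tiny, sc), "too small")
})

test_that("subtype split recovers planted exhausted samples", {
  sd <- small_discovery()
  lab <- sd$disc$assignment$labels
  tr <- truth_labels(sd$cohort)[names(lab)]
  imm <- tr != "non_immune" & lab != "non_immune"
  expect_gte(mean((lab == "exhausted")[imm] == (tr == "exhausted")[imm]), 0.95)
})

test_that("projection is self-consistent and transfers to new cohorts", {
  sd <- small_discovery()
  proj <- project_cohort(sd$disc$reference, sd$cohort$expression)
  expect_identical(proj$provenance, "projected")
  expect_gte(mean(proj$labels == sd$disc$assignment$labels), 0.95)

  co2 <- generate_cohort(small_config(seed = 909))
  proj2 <- project_cohort(sd$disc$reference, co2$expression)
  expect_gte(mean(proj2$labels == truth_labels(co2)[names(proj2$labels)]), 0.9)
})

test_that("a sample equal to a class centroid is assigned that class", {
  sd <- small_discovery()
  ref <- sd$disc$reference
  # build a sample whose transcriptome-wide ranks reproduce the centroid on
  # exemplar genes
  expr <- sd$cohort$expression
  x <- rowMeans(expr)
  x[ref$exemplar_genes] <- stats::quantile(x, probs = ref$centroids[, "non_immune"],
                                           type = 1)
  m <- matrix(x, ncol = 1, dimnames = list(names(x), "probe"))
  p <- project_cohort(ref, m)
  expect_equal(unname(p$labels), "non_immune")
})

test_that("projection demands at least half the exemplar genes", {
  sd <- small_discovery()
  ref <- sd$disc$reference
  expr <- sd$cohort$expression
  drop <- ref$exemplar_genes[seq_len(ceiling(0.6 * length(ref$exemplar_genes)))]
  expect_error(project_cohort(ref, expr[!(rownames(expr) %in% drop), ]),
               "exemplar genes present")
})

test_that("NNLS projection mode agrees with discovery labels", {
  sd <- small_discovery()
  proj <- project_cohort(sd$disc$reference, sd$cohort$expression, mode = "nnls")
  two <- function(v) ifelse(v == "non_immune", "non_immune", "immune")
  expect_gte(mean(two(proj$labels) == two(sd$disc$assignment$labels)), 0.85)
})
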