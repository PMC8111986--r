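# Copy-number burden, gene calls, aneuploidy, mutation filtering and
# signature extraction.

test_that("gene-level calls use the length-weighted mean with strict thresholds", {
  genes <- data.frame(gene = "G1", chromosome = "1", start = 1001, end = 2000)
  call_of <- function(segs) call_gains_losses(segs, genes)["G1", "s1"]
  expect_equal(call_of(seg_row("s1", 1, 1, 5000, 0.31)), "gain")
  expect_equal(call_of(seg_row("s1", 1, 1, 5000, 0.30)), "neutral")  # strict >
  expect_equal(call_of(seg_row("s1", 1, 1, 5000, -0.31)), "loss")
  # half at +0.6, half at 0.0: weighted mean exactly 0.3, still neutral
  segs <- rbind(seg_row("s1", 1, 1, 1500, 0.6), seg_row("s1", 1, 1501, 5000, 0))
  expect_equal(call_of(segs), "neutral")
  # no overlap: neutral with the missing flag
  far <- seg_row("s1", 2, 1, 5000, 1)
  calls <- call_gains_losses(far, genes)
  expect_equal(calls["G1", "s1"], "neutral")
  expect_true(attr(calls, "missing")["G1", "s1"])
})

test_that("fraction of genome altered matches hand computations", {
  s <- rbind(seg_row("a", 1, 1, 100, 0.2), seg_row("a", 1, 101, 400, 0.05))
  fga <- fraction_genome_altered(s)
  expect_equal(fga$fraction_altered, 0.25)
  expect_equal(fga$n_segments, 2)

  s2 <- rbind(seg_row("b", 1, 1, 50, -0.5), seg_row("b", 1, 51, 100, 0.5))
  expect_equal(fraction_genome_altered(s2)$fraction_altered, 1.0)

  s3 <- seg_row("c", 1, 1, 1000, 0)
  expect_equal(fraction_genome_altered(s3)$fraction_altered, 0)

  # splitting a segment in half leaves the fraction unchanged
  whole <- rbind(seg_row("d", 1, 1, 1000, 0.4), seg_row("d", 2, 1, 1000, 0))
  split2 <- rbind(seg_row("d", 1, 1, 500, 0.4), seg_row("d", 1, 501, 1000, 0.4),
                  seg_row("d", 2, 1, 1000, 0))
  expect_equal(fraction_genome_altered(whole)$fraction_altered,
               fraction_genome_altered(split2)$fraction_altered)
})

test_that("aneuploidy counts arms whose weighted mean exceeds the threshold", {
  arms <- data.frame(arm = c("1p", "1q"), chromosome = "1",
                     start = c(1, 1001), end = c(1000, 2000))
  z <- rbind(seg_row("s", 1, 1, 1000, 0), seg_row("s", 1, 1001, 2000, 0))
  expect_equal(aneuploidy_score(z, arms)$aneuploidy_score, 0L)
  one <- rbind(seg_row("s", 1, 1, 1000, 0.4), seg_row("s", 1, 1001, 2000, 0))
  expect_equal(aneuploidy_score(one, arms)$aneuploidy_score, 1L)
  # an arm half amplified, half deleted averages to zero: not counted
  bal <- rbind(seg_row("s", 1, 1, 500, 0.4), seg_row("s", 1, 501, 1000, -0.4),
               seg_row("s", 1, 1001, 2000, 0))
  expect_equal(aneuploidy_score(bal, arms)$aneuploidy_score, 0L)
  # uncovered arm is skipped and reported
  half <- seg_row("s", 1, 1, 1000, 0.4)
  out <- aneuploidy_score(half, arms)
  expect_equal(out$aneuploidy_score, 1L)
  expect_equal(attr(out, "skipped_arms")$s, "1q")
})

test_that("packaged arm table covers 41 arms without overlap", {
  arms <- load_arm_table()
  expect_equal(nrow(arms), 41)
  by_chr <- split(arms, arms$chromosome)
  ok <- vapply(by_chr, function(a) {
    a <- a[order(a$start), ]
    nrow(a) == 1 || all(a$start[-1] > a$end[-nrow(a)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("mutation frequency filter is strict and deduplicates per sample", {
  mk <- function(gene, sample, vc = "Missense_Mutation") {
    data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = sample,
               Variant_Classification = vc)
  }
  cat6 <- do.call(rbind, lapply(paste0("s", 1:6), mk, gene = "A"))
  expect_equal(mutation_frequency_filter(cat6, 100), "A")
  cat5 <- do.call(rbind, lapply(paste0("s", 1:5), mk, gene = "B"))
  expect_equal(mutation_frequency_filter(cat5, 100), character(0))  # exactly 5%
  # recurrent hits in one sample count once
  rec <- rbind(do.call(rbind, lapply(paste0("s", 1:5), mk, gene = "C")),
               mk("C", "s1"), mk("C", "s1"))
  expect_equal(mutation_frequency_filter(rec, 100), character(0))
  # silent-only genes never qualify
  sil <- do.call(rbind, lapply(paste0("s", 1:10), mk, gene = "D", vc = "Silent"))
  expect_equal(mutation_frequency_filter(sil, 100), character(0))
  expect_equal(mutation_frequency_filter(cat6[0, ], 100), character(0))
})

test_that("simulated catalogues reproduce their generating signatures", {
  ref <- reference_signatures()
  # pure signature A
  expo <- matrix(c(1, 0, 0, 0, 0), 5, dimnames = list(colnames(ref), "s1"))
  cat1 <- generate_mutation_catalog(expo, 1000, seed = 21)
  counts <- context_count_matrix(cat1)
  expect_equal(sum(counts), 1000)
  expect_gte(cosine_similarity(counts[, 1], ref[, "SIG_A"]), 0.95)
  # 50/50 mixture
  expo2 <- matrix(c(0.5, 0.5, 0, 0, 0), 5, dimnames = list(colnames(ref), "s1"))
  cat2 <- generate_mutation_catalog(expo2, 2000, seed = 22)
  c2 <- context_count_matrix(cat2)
  expect_gte(cosine_similarity(c2[, 1], ref %*% expo2[, 1]), 0.95)
  # empty catalogue
  expect_equal(nrow(generate_mutation_catalog(expo, 0, seed = 1)), 0)
  bad <- matrix(c(0.6, 0.6, 0, 0, 0), 5)
  expect_error(generate_mutation_catalog(bad, 10), "sum to 1")
})

test_that("signature extraction recovers planted signatures", {
  ref <- reference_signatures()
  set.seed(31)
  mix <- vapply(1:40, function(i) {
    a <- stats::runif(1, 0.2, 0.8); c(a, 1 - a, 0, 0, 0)
  }, numeric(5))
  dimnames(mix) <- list(colnames(ref), paste0("s", 1:40))
  cat2 <- generate_mutation_catalog(mix, 400, seed = 32)
  counts <- context_count_matrix(cat2)
  ext <- suppressWarnings(extract_mutational_signatures(counts, k = 2, seed = 33))
  cs <- vapply(c("SIG_A", "SIG_B"), function(r)
    max(apply(ext$signatures, 2, cosine_similarity, b = ref[, r])), numeric(1))
  expect_gte(min(cs), 0.9)
  # column-stochastic signatures, non-negative exposures
  expect_equal(unname(colSums(ext$signatures)), rep(1, 2))
  expect_true(all(ext$exposures >= 0))
  # reconstruction conserves per-sample totals within 1%
  recon <- colSums(ext$signatures %*% ext$exposures)
  expect_true(all(abs(recon - colSums(counts)) / colSums(counts) < 0.01))
})

test_that("single-signature catalogues are recovered almost exactly at k = 1", {
  ref <- reference_signatures()
  expo <- matrix(rep(c(0, 0, 1, 0, 0), 8), 5,
                 dimnames = list(colnames(ref), paste0("s", 1:8)))
  cat1 <- generate_mutation_catalog(expo, 600, seed = 41)
  counts <- context_count_matrix(cat1)
  ext <- suppressWarnings(extract_mutational_signatures(counts, k = 1, seed = 42))
  expect_gte(cosine_similarity(ext$signatures[, 1], ref[, "SIG_C"]), 0.98)
  expect_equal(ext$match$best_reference, "SIG_C")
})

test_that("group-wise alteration tests match exact references", {
  altered <- rbind(onlyA = rep(c(TRUE, FALSE), c(20, 20)),
                   same = rep(c(TRUE, FALSE), 20),
                   never = rep(FALSE, 40))
  colnames(altered) <- paste0("s", 1:40)
  groups <- rep(c("A", "B"), each = 20)
  res <- differential_alteration_test(altered, groups)
  expect_false("never" %in% res$feature)
  expect_lt(res$p[res$feature == "onlyA"], 1e-6)
  expect_equal(res$p[res$feature == "same"], 1)
})

test_that("null alteration rates rarely pass BH", {
  set.seed(51)
  reps <- replicate(20, {
    altered <- matrix(stats::runif(500 * 40) < 0.3, 500, 40,
                      dimnames = list(paste0("f", 1:500), paste0("s", 1:40)))
    res <- differential_alteration_test(altered, rep(c("A", "B"), each = 20))
    sum(res$q < 0.05)
  })
  expect_lte(mean(reps), 0.05 * 500)
})

test_that("leukocyte-fraction correlation behaves on known structure", {
  x <- 1:20
  res <- leukocyte_cnv_correlation(x, -x)
  expect_equal(res$rho, -1)
  # planted rank correlation of about -0.4 via a Gaussian copula
  set.seed(61)
  z <- stats::rnorm(150)
  y <- -0.42 * z + sqrt(1 - 0.42^2) * stats::rnorm(150)
  est <- leukocyte_cnv_correlation(z, y)$rho
  expect_lt(abs(est - (-0.4)), 0.15)
  expect_error(leukocyte_cnv_correlation(rep(1, 10), 1:10), "constant")
  # per-group output rows
  g <- rep(c("u", "v"), 75)
  res2 <- leukocyte_cnv_correlation(z, y, g)
  expect_equal(res2$group, c("all", "u", "v"))
})
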