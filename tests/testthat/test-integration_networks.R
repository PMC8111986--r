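# Set/join algebra of the multi-omics integration rules.

test_that("miRNA target rule keeps validated-and-doubly-predicted links", {
  defms <- data.frame(feature = c("m1", "m2"))
  validated <- data.frame(mirna = c("m1", "m1", "m2"), gene = c("gA", "gB", "gC"))
  predicted <- data.frame(mirna = c("m1", "m1", "m1", "m2"),
                          gene = c("gA", "gA", "gB", "gC"),
                          db = c("miranda", "mirdb", "miranda", "mirdb"))
  both <- mirna_target_links(defms, validated, predicted)
  expect_equal(both$gene, "gA")                 # gB: one db; gC: one db
  either <- mirna_target_links(defms, validated, predicted, rule = "either")
  expect_setequal(either$gene, c("gA", "gB", "gC"))
  expect_error(mirna_target_links(defms[0, , drop = FALSE], validated, predicted),
               "no differential")
})

test_that("randomized tables reproduce the brute-force triple intersection", {
  set.seed(1)
  mirs <- paste0("m", 1:15); genes <- paste0("g", 1:30)
  validated <- unique(data.frame(mirna = sample(mirs, 120, TRUE),
                                 gene = sample(genes, 120, TRUE)))
  predicted <- unique(data.frame(mirna = sample(mirs, 240, TRUE),
                                 gene = sample(genes, 240, TRUE),
                                 db = sample(c("miranda", "mirdb"), 240, TRUE)))
  defms <- data.frame(feature = mirs[1:8])
  res <- mirna_target_links(defms, validated, predicted)
  brute <- 0
  for (i in seq_len(nrow(validated))) {
    mi <- validated$mirna[i]; ge <- validated$gene[i]
    if (!(mi %in% defms$feature)) next
    dbs <- unique(predicted$db[predicted$mirna == mi & predicted$gene == ge])
    if (all(c("miranda", "mirdb") %in% dbs)) brute <- brute + 1
  }
  expect_equal(nrow(res), brute)
})

test_that("lncRNA network joins chains and keeps degree-0 miRNAs", {
  e1 <- data.frame(lncrna = c("l1", "l2"), mirna = c("m1", "m2"))
  e2 <- data.frame(mirna = "m1", gene = "gA")
  net <- lncrna_network(c("l1", "l2"), e1, e2, degs = "gA")
  expect_equal(nrow(net$lnc_mir), 2)
  expect_equal(net$mir_gene$gene, "gA")
  expect_true(net$mir_gene$is_deg)
  # m2 has no gene edges but keeps its lncRNA edge; degree 0
  expect_equal(net$mir_degree$n_genes[net$mir_degree$Var1 == "m2"], 0L)
  expect_equal(net$n_components, 2)
})

test_that("random network joins match brute-force counts", {
  set.seed(2)
  e1 <- unique(data.frame(lncrna = sample(paste0("l", 1:10), 60, TRUE),
                          mirna = sample(paste0("m", 1:12), 60, TRUE)))
  e2 <- unique(data.frame(mirna = sample(paste0("m", 1:12), 80, TRUE),
                          gene = sample(paste0("g", 1:25), 80, TRUE)))
  dl <- paste0("l", 1:4)
  net <- lncrna_network(dl, e1, e2, degs = character(0))
  kept1 <- e1[e1$lncrna %in% dl, ]
  expect_equal(nrow(net$lnc_mir), nrow(kept1))
  expect_equal(nrow(net$mir_gene), nrow(e2[e2$mirna %in% kept1$mirna, ]))
})

test_that("multiomics venn honours the layer threshold", {
  hits <- list(DEG = c("a", "b", "c"), CNV = c("b", "c", "d"),
               SNP = c("c", "e"), protein = c("f"))
  expect_setequal(multiomics_venn(hits, 2)$genes, c("b", "c"))
  expect_setequal(multiomics_venn(hits, 1)$genes, sort(unique(unlist(hits))))
  expect_equal(multiomics_venn(hits, 4)$genes, character(0))
  expect_error(multiomics_venn(hits, 5), "min_layers")
  expect_error(multiomics_venn(hits["DEG"], 1), ">= 2 layers")
  # brute force on random layers
  set.seed(3)
  rl <- lapply(1:4, function(i) sample(letters, 10))
  names(rl) <- paste0("L", 1:4)
  mv <- multiomics_venn(rl, 2)
  brute <- names(which(table(unlist(lapply(rl, unique))) >= 2))
  expect_setequal(mv$genes, brute)
})

test_that("over-representation matches exact hypergeometric enumeration", {
  universe <- paste0("g", 1:10)
  pathways <- list(P = paste0("g", 1:4), Q = paste0("g", 7:10))
  res <- overrepresentation_test(paste0("g", 1:4), universe, pathways)
  # enumeration: drawing 4 from 10 with 4 white; P(X >= 4) and P(X >= 0)
  p_exact <- choose(4, 4) * choose(6, 0) / choose(10, 4)
  expect_equal(res$p[res$pathway == "P"], p_exact)
  expect_equal(res$p[res$pathway == "Q"], 1)  # disjoint: P(X >= 0) = 1
  expect_equal(which.min(res$p), which(res$pathway == "P"))
  # empty list: all p = 1
  empty <- overrepresentation_test(character(0), universe, pathways)
  expect_true(all(empty$p == 1))
  expect_error(overrepresentation_test("zz", universe, pathways), "subset")
})

test_that("overlap tail sums match manual enumeration on a balanced toy", {
  universe <- paste0("g", 1:12)
  pw <- list(P = paste0("g", 1:6))
  lst <- paste0("g", c(1, 2, 7, 8))
  res <- overrepresentation_test(lst, universe, pw)
  manual <- sum(vapply(2:4, function(k)
    choose(6, k) * choose(6, 4 - k) / choose(12, 4), numeric(1)))
  expect_equal(res$p, manual)
})

test_that("pathway-gene network emits one edge per list-and-pathway member", {
  enr <- data.frame(pathway = "P", overlap = 2, pathway_size = 3,
                    p = 0.01, q = 0.01)
  pw <- list(P = c("a", "b", "c"))
  net <- pathway_gene_network(enr, c("a", "b", "z"), pw)
  expect_equal(nrow(net$edges), 2)
  expect_false("z" %in% net$nodes$id)   # in list but no enriched pathway
  expect_setequal(net$edges$gene, c("a", "b"))
})
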