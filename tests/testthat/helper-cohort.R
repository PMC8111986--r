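# Shared fixtures, built in code. The full-scale discovery run is expensive
# and memoized so several tests can interrogate the same analysis.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) assign(key, fn(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

small_config <- function(seed = 1, ...) {
  cohort_config(n_samples = 80, n_genes = 600, seed = seed, ...)
}

# truth labels in the assignment's vocabulary
truth_labels <- function(cohort) {
  map <- c(active = "active_immune", exhausted = "exhausted",
           non_immune = "non_immune")
  out <- map[cohort$truth$labels]
  names(out) <- names(cohort$truth$labels)
  out
}

small_discovery <- function() cached("small_disc", function() {
  co <- generate_cohort(small_config(seed = 42))
  disc <- suppressWarnings(discover_immune_classes(
    co$expression, co$gene_sets[1:5], co$gene_sets$activated_stroma,
    n_var_genes = 400, n_restarts = 2, max_iter = 400, n_resamples = 40,
    seed = 43))
  list(cohort = co, disc = disc)
})

default_discovery <- function() cached("default_disc", function() {
  co <- generate_cohort(cohort_config())
  disc <- suppressWarnings(discover_immune_classes(
    co$expression, co$gene_sets[1:5], co$gene_sets$activated_stroma,
    seed = 11))
  list(cohort = co, disc = disc)
})

# toy SEG table builder
seg_row <- function(sample, chrom, start, end, mean, probes = 10) {
  data.frame(Sample = sample, Chromosome = as.character(chrom), Start = start,
             End = end, Num_Probes = probes, Segment_Mean = mean)
}
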