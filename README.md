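# immunoclass

Bulk tumour expression profiles are mixtures of malignant cells, stroma and
immune infiltrate. Whether a tumour's microenvironment is immunologically
"hot" — and whether that infiltrate is functional or exhausted — shapes
prognosis and the odds that checkpoint blockade will work. `immunoclass`
implements an expression-based immune classification of bulk tumour cohorts
for researchers who have a gene-by-sample matrix (plus, optionally,
copy-number segments, somatic mutations, miRNA/lncRNA/protein tables and
clinical follow-up) and want to stratify samples into:

* an **immune class** — enriched for immune-cell signatures, cytolytic
  activity and type I IFN response — versus a **non-immune class**, and
* within the immune class, an **active-immune** subtype versus an
  **exhausted** subtype marked by an activated-stroma / TGF-β /
  wound-healing programme and worse survival.

## Method

The core is *virtual microdissection*: non-negative matrix factorization of
the expression matrix X (genes × samples, non-negative),

    X ≈ W H,   W ∈ R^(g×k)_{≥0},  H ∈ R^(k×s)_{≥0},  k = 3,

fitted by Kullback–Leibler multiplicative updates (Brunet variant, NNDSVD
seeding by default, random restarts available). The three factors resolve
tumour, stroma and immune compartments. The immune factor is the one whose
coefficient row correlates best with a per-sample immune enrichment score —
a rank-weighted single-sample GSEA (ssGSEA) running sum

    ES = Σ_i ( P_in(i) − P_out(i) ),   P_in weighted by rank^α (α = 0.25),

over user-supplied immune gene sets. Genes loading specifically on the
immune factor (*exemplar genes*, specificity ratio ≥ 2) feed a resampled
consensus clustering that defines the immune vs non-immune partition; the
immune class is then split into active vs exhausted by an exact 1-D
two-means on the activated-stroma ssGSEA score. External cohorts are
projected onto the discovered classes by nearest centroid in per-sample
rank space (or NNLS onto W).

Around the classification, the package provides the accompanying analysis
toolkit: differential expression per omics layer (Welch t / Wilcoxon, BH
FDR, |log2 FC| thresholds), preranked GSEA with gene-label permutation FDR,
copy-number burden (fraction of bases with |log2 CN| > 0.1), gene-level
gain/loss calls (|seg mean| > 0.3), arm-level aneuploidy scores,
96-trinucleotide-context mutational-signature extraction (NMF with cosine
matching against a reference), miRNA-target and lncRNA–miRNA–mRNA network
rules, ≥2-of-n multi-omics integration, hypergeometric over-representation,
and cohort statistics (chi-square/Fisher with "Unknown" kept as a category,
ANOVA + LSD, exact Wilcoxon, Kaplan–Meier, log-rank, propensity-score
matching).

A fully parameterised synthetic-cohort generator plants three expression
factors, class-linked clinical covariates, survival hazards, copy-number
profiles and signature-mixture mutation catalogues, so the whole pipeline
is testable end to end against known ground truth.

## Worked example

```r
library(immunoclass)

cfg    <- cohort_config(n_samples = 120, n_genes = 800, seed = 7)
cohort <- generate_cohort(cfg)

immune_sets <- cohort$gene_sets[c("immune_signature", "CD8_T_cells",
                                  "B_cells", "Macrophages", "type_I_IFN")]
res <- discover_immune_classes(cohort$expression, immune_sets,
                               cohort$gene_sets$activated_stroma,
                               n_var_genes = 600, seed = 7)
class_proportions(res$assignment)
#>           class count percent
#> 1 active_immune    64   53.33
#> 2     exhausted    31   25.83
#> 3    non_immune    25   20.83

cl <- cohort$clinical
logrank_test(cl$time, cl$event, res$assignment$labels[cl$sample])
#> $statistic 13.4451   $df 2   $p 0.0012
```

The three reported classes here coincide exactly with the generator's
planted labels (64 active / 31 exhausted / 25 non-immune), and the log-rank
test recovers the planted survival difference (exhausted hazard ratio 2.2).
`res$reference` can be passed to `project_cohort()` to classify an
independent cohort, and `run_pipeline()` drives all stages (classification,
differential layers, genomic scores, signatures, integration, statistics)
from one config list or YAML file, writing per-stage TSVs and a manifest.

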