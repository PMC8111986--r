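Package: immunoclass
Title: Immune Molecular Classification of Tumours by NMF Virtual Microdissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers an expression-defined immune class in bulk tumour
    cohorts by non-negative matrix factorization (virtual microdissection),
    characterizes it with single-sample gene set enrichment scores and
    consensus clustering, and splits it into active-immune and exhausted
    subtypes by an activated-stroma signature. Includes copy-number burden
    and arm-level aneuploidy scores, mutational-signature extraction from
    96-trinucleotide-context catalogues, differential analysis across omics
    layers with preranked GSEA, miRNA/lncRNA network integration rules, the
    accompanying cohort statistics (contingency tests, ANOVA with LSD,
    Kaplan-Meier and log-rank, propensity-score matching), and a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
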