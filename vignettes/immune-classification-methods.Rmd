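---
title: "Immune classification of bulk tumour cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune classification of bulk tumour cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `immunoclass`, the choices made
where the methodology was genuinely open, and what the synthetic cohorts
do and do not demonstrate about real data.

## The mixture model behind virtual microdissection

Bulk expression is modelled as a non-negative mixture, `X ≈ W H`, with
`k = 3` factors intended to absorb the tumour, stroma and immune
compartments of the tissue. The factorization minimizes generalized
Kullback–Leibler divergence by the classic multiplicative updates. The
assumptions that matter:

* **Non-negativity.** Input must be on a non-negative scale (e.g.
  log2(x+1) of normalized counts or array intensities). Negative entries
  are rejected rather than clipped.
* **Compartments mix additively.** Sample heterogeneity is assumed to be
  dominated by compartment proportions, not by gene-level rewiring; this
  is what makes exemplar genes of the immune factor meaningful cohort-wide.
* **Rank 3 is a modelling decision**, not an estimate. `rank_diagnostics()`
  provides cophenetic-correlation and reconstruction-error curves if a user
  wants to challenge it on their cohort.

Before factorization, genes are filtered to the top `n_var_genes = 1500`
by median absolute deviation. MAD is robust to the minority of highly
expressed outlier samples; the cutoff of 1500 follows common practice for
expression NMF and is exposed.

### Initialization

Multiplicative updates only shrink the divergence, so the starting point
decides which local optimum is reached. Two modes are provided:

* `init = "nndsvd"` (default): non-negative double SVD seeding. It is
  deterministic and, in our factor-recovery experiments, consistently
  lands in the basin where the immune and stroma factors stay separated.
* `init = "random"` with `n_restarts` uniform starts, keeping the lowest
  final divergence.

The default is NNDSVD for an identifiability reason worth spelling out:
exhausted-subtype samples load on the immune *and* stroma factors
simultaneously, so the likelihood surface has nearly equivalent optima in
which the stroma factor absorbs a slice of the immune profile. Those mixed
optima can have marginally *lower* divergence than the well-separated one,
so "more random restarts" does not cure the problem — a better-placed
single start does. The package's acceptance checks measure this directly
(minimum matched cosine between fitted and planted basis columns).

Numerical guards: `1e-12` inside update denominators; convergence when the
relative divergence change per iteration falls below `tol = 1e-6`;
`max_iter = 500` with a warning (not an error) on non-convergence; the
objective trace is recorded per iteration and tested to be non-increasing.

## ssGSEA scores

Enrichment of a gene set S in one sample ranks genes by decreasing
expression and accumulates `ES = Σ_i (P_in(i) − P_out(i))`, where `P_in`
steps by `rank_weight^α` at members of S (normalized to the in-set total)
and `P_out` by `1/(N−|S|)` elsewhere. Scores depend only on within-sample
ranks, hence are invariant to monotone transforms and comparable across
heterogeneously scaled samples.

* `α = 0.25` is the package default. The exponent is not pinned by the
  classification itself; `α = 0` gives the unweighted KS-style statistic,
  larger α emphasizes the extremes. It is surfaced in `ScoringConfig`-style
  arguments everywhere scores are computed.
* Ties are broken by gene identifier (lexicographic, radix sort) so scores
  are bit-reproducible across platforms and runs.
* A set with no genes in the matrix yields an `NA` row plus a warning — a
  per-set error record rather than a global failure; a set equal to the
  whole universe is an error because `P_out` is undefined.
* The immune enrichment score is the mean ssGSEA score over the supplied
  immune sets. Which sets compose it is deliberately a user input: the
  package ships planted sets for its synthetic cohorts, not a curated
  human panel.

## From factors to classes

1. **Immune factor** = argmax over factors of the Pearson correlation
   between the factor's coefficient row and the immune score. Two factors
   within `1e-9` of each other raise an ambiguity error rather than a
   silent pick.
2. **Exemplar genes**: ranked by basis weight on the immune factor,
   retained when that weight is at least `min_ratio = 2` times the gene's
   best weight on any other factor; top `m = 150` kept. Both knobs are
   exposed; "weighting" alone would also admit genes shared with stroma,
   which is exactly what the specificity ratio suppresses.
3. **Consensus clustering** on exemplar genes: `n_resamples = 100`
   subsamples of 80% of samples, average-linkage hierarchical clustering,
   co-assignment frequencies, final cut of `1 − consensus` at k = 2.
   The *feature space and distance* were the one genuinely open design
   point. We use Euclidean distance on exemplar-gene rows of the
   per-sample, transcriptome-wide rank-normalized matrix. The more common
   `1 − Pearson` between samples (retained as `dist_method = "pearson"`,
   with per-gene median centering) keys on the *shape* of deviations, and
   on cohorts whose exemplar block is driven by a single factor it is
   provably uninformative: every sample correlates with every other
   through the shared profile, and after centering the split tracks the
   per-gene median inside the majority class. Rank-Euclidean keeps the
   *level* of immune expression — the actual class signal — and is the
   same space the projection operates in, so discovery and projection are
   mutually consistent.
4. **Immune vs non-immune**: the cluster with the higher mean immune
   score. **Active vs exhausted**: exact 1-D two-means (scan over sorted
   split points; deterministic, shift-invariant) on the activated-stroma
   ssGSEA score within the immune class; the higher-stroma cluster is
   exhausted. Degenerate inputs (constant scores, immune class < 4) are
   errors, not silent single-cluster outputs.

## Projection of external cohorts

New samples are classified on the shared exemplar genes (≥ 50% overlap
required, otherwise an error lists what is missing):

* **Centroid mode (default)**: per-sample ranks over the new cohort's full
  transcriptome, restricted to shared exemplar genes, nearest discovery
  centroid by Euclidean distance. Ranks-over-the-transcriptome carry the
  level signal (immune samples rank exemplar genes uniformly high) while
  remaining platform-robust. A Pearson-to-centroid rule on
  exemplar-restricted ranks was rejected for the same collinearity reason
  as above: both class centroids share the exemplar profile's shape, so
  correlation cannot tell them apart on factor-structured data.
* **NNLS mode**: non-negative least squares of each sample onto the
  discovery basis `W`; immune when the immune factor's relative weight
  exceeds the midpoint of the discovery classes' means.

Subtypes are then assigned by the discovery stroma-score threshold. This
assumes comparable score scales between cohorts, which holds when gene
universes are similar; with drastically smaller platforms the threshold
should be re-derived.

## Differential layers, GSEA, genomics, integration

* Differential expression uses a plain Welch t (or Wilcoxon) with BH
  adjustment and a two-sided `|log2 FC| > 1` gate; the pass rule is
  `adj p < 0.05 ∧ |logFC| > 1`. No empirical-Bayes variance moderation is
  attempted — the package stands alone and says so. Zero-variance features
  are flagged, not dropped. Inputs are assumed log-scale; the logFC
  semantics are meaningless otherwise.
* Preranked GSEA uses the weighted-KS maximum deviation, gene-label
  permutations (robust when class sizes are small), sign-stratified NES
  and FDR. `n_perm < 10` is refused.
* Copy-number rules are implemented with strict inequalities exactly as
  printed in their sources: gains `> 0.3`, losses `< −0.3`, burden and
  arm calls `> 0.1` in |log2 CN|. Gene and arm values are length-weighted
  means over overlapping segments; an arm half-amplified and half-deleted
  therefore averages to neutral — a documented consequence of averaging
  rather than discrete-call counting, which would need allele-specific
  input the package does not consume. Mutation-frequency filtering is
  strictly `> 5%` of the cohort with per-sample deduplication.
* Mutational signatures are extracted by the same KL-NMF engine on
  96-context counts; signatures are reported column-stochastic with
  compensated exposures and cosine-matched against a packaged reference.
  The packaged reference is **synthetic** (deterministic peaked profiles)
  so that simulation and matching are self-contained; users interpreting
  real catalogues should supply an empirical reference table.
* Integration rules are pure set algebra (validated ∧ both-database
  predicted by default, with "either" selectable; ≥ 2-of-n layers), so
  they are tested against brute-force joins.
* Cohort statistics keep "Unknown" as a genuine category by default —
  recomputation of published clinical tables only reproduces their
  p-values when Unknown rows are included and no continuity correction is
  applied, and the package follows that convention (a drop-unknown option
  is a one-line subset away). The Wilcoxon test enumerates all group
  assignments exactly when `n ≤ 12` (tie-safe, permuting observed average
  ranks); beyond that a tie- and continuity-corrected normal
  approximation is used. Propensity matching is greedy 1:1
  nearest-neighbour on the logit propensity within a `0.2·sd` caliper,
  treated processed in decreasing propensity order for determinism;
  balance is reported as standardized mean differences before/after.
  Greedy caliper matching leaves residual imbalance when overlap is poor
  — the tests demonstrate balance in a strong-but-overlapping confounding
  regime, not under extreme separation.

## What the synthetic cohorts emulate — and what they do not

`cohort_config()` defaults are the package's reference study conditions:
293 samples in proportions 153/74/64 (active/exhausted/non-immune), three
planted factors with the exhausted subtype loading on immune *and* stroma,
clinical covariates (HPV status, smoking, stage, radiation, histology)
drawn with class-dependent probabilities including explicit "Unknown"
levels, exponential survival with hazard ratios 1 / 2.2 / 1.4 and uniform
censoring on [0, 5000] days, per-class copy-number profiles (expected
fraction altered 0.12 / 0.30 / 0.20; most segments in non-immune), and
mutation catalogues drawn from fixed mixtures of the packaged reference
signatures (Poisson totals 60 / 150 / 100).

Two generator details deserve justification:

* **Module-level noise** (`module_sd = 0.4`): each planted immune
  submodule (and the stroma block) is multiplied per sample by a mean-one
  lognormal factor. Without it the exemplar block is exactly rank-1 —
  every sample an exact scalar multiple of the same profile — a
  degeneracy real infiltrates do not exhibit and under which *no*
  correlation-type similarity can work. Setting `module_sd = 0` together
  with `noise_sd = 0` restores the exact `W H` identity used by the
  zero-noise tests.
* **Off-factor loadings** are small residuals (`U(0, 0.1)`–`U(0, 0.2)`),
  per the planted design: active samples load on the immune factor only,
  non-immune on the tumour factor only.

What passing the suite on these cohorts shows: the pipeline recovers
planted compartments, classes, subtypes, signatures and hazards under the
generative model it assumes, at realistic cohort sizes, deterministically
per seed. What it does not show: robustness to batch effects, platform
mixtures, tumour-purity gradients, non-additive compartment interactions,
or immune programmes that do not factorize — none of which the generator
emulates. Results on real cohorts should be accompanied by the rank
diagnostics and consensus matrices the package emits.

## Problem sizes

The shipped tests run the full discovery chain at the default 293-sample,
2000-gene scale once (memoized across test files) and use 60–150-sample
cohorts for module-level properties; null simulations use 500–1000
features. These sizes were chosen as the smallest at which the measured
properties are stable across seeds.

## Known limitations

* k-NMF identifiability is inherently weak when a subtype loads on two
  factors; NNDSVD mitigates but does not remove this.
* The stroma-score subtype threshold transfers across cohorts only to the
  extent the score scales match.
* BH is applied per layer, not across layers.
* Cox modelling, GISTIC-style peak calling, allele-specific copy number,
  deconvolution against empirical cell references and external database
  retrieval are out of scope; interaction tables and pathway collections
  are consumed as user-provided inputs.
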