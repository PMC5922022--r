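---
title: "Adjusting for stroma confounding in bulk prostate expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting for stroma confounding in bulk prostate expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromabalance)
```

## The problem

Bulk prostate tissue is a mixture of three compartments: cancer cells,
benign (normal) epithelium and stroma — the connective and supportive
tissue between the glands. In cancer-vs-normal differential expression the
proper reference for cancer cells is the benign epithelium, but routine
sampling introduces a systematic bias: specimens labelled "normal" carry on
average substantially more stroma than the cancer specimens. Any gene whose
expression differs between stroma and epithelium then shows up as
"differentially expressed in cancer" even if the cancer cells themselves
are unremarkable — and, conversely, a real cancer-vs-epithelium signal can
be masked. The canonical confounded pattern is a gene highly expressed in
benign epithelium, intermediately in cancer and weakly in stroma: the
stroma excess in the normal group drags the normal-group average down
toward the cancer-group average and the true downregulation washes out.

`stromabalance` implements a stratification-based correction that needs no
per-sample deconvolution:

1. In a cohort where every sample has pathologist-assessed tissue
   percentages, split each class at its stroma median and form a
   **balanced** dataset (highest-stroma cancers + lowest-stroma normals,
   matched average stroma) and an **unbalanced** dataset (the complementary
   halves, maximal stroma difference). Equal group sizes keep the two
   contrasts at the same statistical power, so p-values are directly
   comparable gene by gene.
2. Rank genes by `p_score = p_unbal / p_bal^2`. A stroma-characteristic
   gene is strongly significant only when the groups differ in stroma, so
   it has a small `p_unbal` and a large `p_bal`. The squared denominator
   penalizes genes that are significant in *both* contrasts: a gene at
   `1e-5 / ~1` is a better stroma-marker candidate than one at
   `1e-20 / 1e-15`, despite the equal ratio. The top genes per direction
   form the stroma-up and stroma-down gene-sets. Genes belonging to the
   pathway under study are removed from these sets to avoid circularity.
3. Score stroma content of any sample — in cohorts *without*
   histopathology — by a single-sample enrichment statistic over the
   stroma sets, and stratify those cohorts by the score exactly as in
   step 1.
4. Combine cohorts in a rank-based meta-analysis (0–100 rank
   normalization, class-balanced mean centering, pooled Mann–Whitney
   tests) for the unstratified, balanced and unbalanced contrasts.

The balanced contrast isolates cancer-vs-epithelium biology; the
unbalanced contrast highlights cancer-vs-stroma differences; comparing a
gene across the two tells you which of those drives its significance.

## The single-sample enrichment score

For one sample, genes of the shared universe are ordered by decreasing
expression (ties broken by gene id for determinism) and an unweighted
Kolmogorov–Smirnov running sum is accumulated: members of the gene-set
step `+1/|S|`, non-members `-1/(N-|S|)`; the score is the signed maximum
deviation from zero. When the walk attains `+m` and `-m` simultaneously
the first peak reached is returned. We use the unweighted (rank-only)
statistic rather than an expression-weighted variant deliberately: the
score must be comparable across microarray and RNA-seq platforms, and a
rank-only statistic is invariant under any strictly monotone per-sample
transform, so platform-specific intensity scales cannot leak in.

The per-sample stroma score is `ES(up-set) − ES(down-set)`, computed for a
ladder of set sizes (by default the top 100, 150, …, 500 and 1000 genes
of each direction), normalized per size to 0–100 across the cohort's
samples, and averaged over sizes. The ladder makes the score robust to the
arbitrary set-size cutoff; `score_stability()` reports the per-sample
spread across sizes. Because the 0–100 normalization is within-cohort,
scores are *relative*: they order samples inside one cohort but carry no
absolute meaning across cohorts (cohort baselines differ substantially).
Consequently stratification is always performed per cohort, which is all
the method needs. `calibrate_to_histopathology()` provides the optional
least-squares mapping from score to stroma percentage where histopathology
exists; we regress histopathology on score (the direction a user predicts
in) and clip predictions to [0, 100].

## The rank statistics

Per-gene tests are two-sided Mann–Whitney throughout — per cohort and in
the meta-analysis — so the whole stack is rank-based and shares the same
invariances as the scoring. Groups with at least 8 samples each use the
tie-corrected normal approximation without continuity correction; smaller
groups use the exact null distribution (the exact Wilcoxon CDF for
tie-free data, full enumeration of label assignments when ties are present
and at most 1e5 assignments exist, the corrected approximation beyond
that). Constant genes get `p = 1` and direction `"up"` by convention.
Significance ranks break p-value ties lexicographically by gene id so
whole-pipeline runs are reproducible byte for byte.

The meta-analysis rank-normalizes each gene to 0–100 within each cohort
(average ranks for ties, affine map of rank 1 to 0 and rank *n* to 100)
and centers on the equal-weight average of the two class means,
`(mean_cancer + mean_normal)/2`. Equal weighting is what makes the
centering invariant to each cohort's cancer/normal imbalance — with a 10:1
class ratio a grand-mean centering would be dominated by the cancer class
and shift normal samples of different cohorts differently. For cohorts
lacking one class entirely only plain mean centering is possible
(`weighted = FALSE`). Genes absent from some cohorts are tested on the
cohorts that contain them. Benjamini–Hochberg correction is applied at a
global gene count `m_total` (the union of genes across cohorts), which is
conservative for genes measured in fewer cohorts; per-cohort analyses
default to the cohort's own gene count, and both choices are exposed.

## The synthetic cohort generator

Real cohorts with histopathology are access-controlled, so validation runs
on synthetic cohorts that emulate the tissue-mixture mechanics. Each gene
gets a baseline log2 expression `mu ~ N(7, 1.5)` and three tissue profiles
(cancer, stroma, epithelium). A sample's expression is the log of the
tissue-fraction-weighted sum of the *linear-scale* profiles — mixing
happens in linear space because bulk RNA from compartments adds
physically — plus `N(0, noise_sd)` noise and a cohort-level baseline
offset. Tissue fractions are Dirichlet draws around class-specific means;
normal samples mix only stroma and epithelium (their cancer fraction is
exactly zero), cancer samples mix all three with the non-stroma mass split
65:35 between cancer and epithelium.

Planted gene classes:

* `stroma_up` / `stroma_down`: the stroma profile is shifted by
  ±`delta_stroma` (default 2 on log2 scale);
* `cancer_de_down`: profiles ordered epithelium > cancer > stroma with
  half-gap `delta_cancer` (default 1.5) — the confounded pattern above;
* `cancer_de_up`: the mirror ordering;
* `null` genes share one profile across tissues, so tissue composition
  carries no signal for them. This is deliberately idealized: it gives the
  null calibration tests a clean uniform null, whereas in real tissue
  essentially every gene differs somewhat between compartments.

Reference conditions (the package defaults): 2000 genes, 100 cancer + 50
normal samples per cohort, 10% stroma-up, 10% stroma-down and 5%
confounded cancer genes, mean stroma fraction 0.50 in normals vs 0.25 in
cancers (the sampling bias), Dirichlet concentration 10 (histopathology-like
spread of roughly ±15 percentage points), noise sd 0.5. Effect sizes were
chosen once so that planted effects are detectable at these sample sizes
with this noise; they are calibration choices, not measured tissue values.
Multi-cohort suites share one planted truth (profiles and gene classes)
and draw samples, noise and baseline shifts per cohort, emulating
independent cohorts assaying the same biology. Validation tests and the
acceptance script use five-cohort suites at these conditions with reduced
set-size ladders (top 50–200 of a 2000-gene universe) matching the scale
of the simulated gene space.

What passing these tests shows — and does not. Recovery of planted classes
shows the pipeline's machinery (p_score ranking, enrichment scoring,
stratification, meta-analysis) does what it claims under a faithful
mixture model with known truth. It does not certify performance on real
tissue, where reactive stroma near tumors differs from normal stroma (a
fourth compartment we do not model), probe-level artifacts exist (probe
collapse is therefore tested on hand-built fixtures), and no gene is
perfectly tissue-neutral.

## Numerical and design choices

* **Sort determinism.** All lexicographic orderings use C-locale radix
  sorting; p-value and stroma ties break by gene/sample id. Two runs with
  one config are byte-identical.
* **Odd class counts** drop the median sample so the balanced and
  unbalanced halves stay equal-sized; a `fraction` argument exposes
  non-half splits.
* **Residual imbalance.** Half-splitting minimizes but does not eliminate
  the stroma gap when the class means are far apart (0.25 vs 0.50 leaves a
  few percentage points of residual difference). This is inherent to the
  design, and is why balanced-analysis improvements fluctuate across
  simulation seeds.
* **Exclusion lists.** Removing the study pathway from the stroma sets
  prevents circularity. In the simulations the planted
  cancer-vs-epithelium genes play that role: their confounded profile
  makes them genuine stroma covariates, and leaving them in measurably
  contaminates the derived stroma-up set. Exclusion happens before
  truncation, so sets stay at full size. Re-introducing excluded genes
  perturbs only the set tails; sample assignments are expected to be
  nearly — not provably exactly — unchanged, since a sample scoring at the
  class median can flip.
* **p_score domain.** p-values of exactly 0 are rejected (they cannot
  arise from the Mann–Whitney tests, which are floored at the smallest
  positive double); the formula uses uncorrected p-values, as correction
  happens downstream of gene-set derivation.
* **Single-sample cohorts** cannot be 0–100 normalized; the stroma score
  is fixed at 50 with a warning rather than failing, so downstream
  bookkeeping survives degenerate inputs.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
suite <- generate_suite(cohort_config(seed = 42), n_cohorts = 5)
study_genes <- subset(planted_de_table(suite[[1]]$truth),
                      grepl("cancer_de", class))$gene_id
cfg <- list(
  cohorts = lapply(names(suite), function(cid)
    list(matrix = suite[[cid]]$matrix,
         annotation = suite[[cid]]$annotation,
         cohort_id = cid,
         histopathology = cid %in% names(suite)[1:2])),
  n_top = 200, sizes = c(50, 100, 150, 200),
  exclude = study_genes, seed = 7)
bundle <- run_pipeline(cfg)

# stroma confounding in, stroma confounding out:
mean_rank <- function(de) mean(de$rank[match(study_genes, de$gene_id)])
mean_rank(bundle$meta_de$unstratified)   # planted cancer genes buried
mean_rank(bundle$meta_de$balanced)       # recovered near the top
```

## Known limitations

* Stroma is treated as one homogeneous compartment; reactive
  (tumor-adjacent) stroma is not modelled.
* Scores are within-cohort relative measures; no absolute cross-cohort
  stroma percentage is produced, and none is needed for stratification.
* The meta-analysis is a single pooled rank test, not a random-effects
  model; heterogeneity of effect across cohorts is not quantified.
* Gene identifiers are opaque case-sensitive strings; cross-platform
  symbol harmonization must happen upstream.
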