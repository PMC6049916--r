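---
title: "Cell-type composition indices: model, simulator, and downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type composition indices: model, simulator, and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendr)
```

## The problem

Bulk transcriptomic data from macro-dissected brain tissue averages over a
mixture of cell types — neurons of several classes, astrocytes,
oligodendrocytes, microglia, vascular cells, and trapped blood. When the
mixture itself shifts between samples (different dissections, different
agonal states, different diagnoses), genes expressed preferentially in one
cell type rise and fall together, and a differential-expression analysis
cannot tell a change in *cell-type balance* from a change in *cell-intrinsic
regulation*. This package estimates the relative cell-type balance of each
sample from curated marker genes, so that composition can be examined
directly, related to subject covariates, and, where appropriate, adjusted
for in per-gene models.

## The index model

Let $x_{ts}$ be log2-scale, normalized expression of transcript $t$ in
sample $s$. The pipeline in `cell_type_indices()` is:

1. **Row standardization.** Each transcript row is centered and scaled
   across samples to mean 0, sd 1 (sample sd, $n-1$ denominator):
   $z_{ts} = (x_{ts} - \bar x_t)/\hat\sigma_t$. This stops highly variable
   transcripts from dominating the averages that follow. Zero-variance rows
   have no z-score and are dropped, with counts reported.
2. **Transcript-to-gene collapse.** Rows mapping to the same gene symbol
   are averaged per sample and the averaged row is re-standardized to mean
   0, sd 1. The collapse is global (all annotated rows), not per marker
   set. We read "re-scaled" as a second z-score: averaging unit-sd rows
   shrinks the sd below 1 by an amount that depends on the number of
   probes, and a second standardization removes that artifact so genes
   measured by many probes are not quietly down-weighted.
3. **Publication-specific indices.** For each reference publication's
   marker set $G_p$, the index of sample $s$ is the mean z-value
   $\mathrm{CTI}_{ps} = \frac{1}{|G_p|}\sum_{g \in G_p} z_{gs}$, one column
   per publication tag.
4. **Consolidation.** Genes claimed by two or more *primary categories*
   (across publications) are removed, publication indices are recomputed on
   the filtered sets, and the publication **columns** are averaged within
   each of the ten primary categories. We average columns rather than
   pooling all of a category's genes into one set: averaging columns gives
   each reference study equal weight regardless of its list length, which
   is the behaviour the per-publication indices are designed to preserve.

The result is relative and unitless: each index column has mean 0 across
the samples of the dataset and sd in $(0, 1]$. An index says a sample has
more or less of a cell type's specific expression *than the other samples
in the same matrix* — it is not an absolute proportion, and it cannot
separate "more cells" from "more transcription per cell".

### Tunable parameters

* `min_genes` (default 3, hard floor 1): minimum marker genes a
  publication set must match in the data before its index is computed. A
  one-gene "index" is just that gene's z-score; three is a minimal
  hedge against single-gene artifacts while keeping small curated sets
  usable.
* `exclude`: publication tags dropped before scoring. The curated resource
  has a known usage profile that omits a few weaker reference sets; the
  tag list is user-supplied because it is a property of the database
  version in use, not of the algorithm.
* `missing` (`"drop"`/`"impute"`): rows with non-finite values are dropped
  by default (the method expects fully preprocessed input); optional
  per-row mean imputation is available for nearly complete matrices.
* `keep_overlaps`: retains cross-category genes during consolidation, for
  comparison with the filtered default.

### Numerical conventions

Standard deviations use the $n-1$ denominator everywhere, so results match
`scale()` and the closed-form oracles in the tests. Zero-variance rows and
collapsed genes are dropped, never imputed. Output column order is fixed
(publication tags alphabetical, categories in `CELL_TYPE_CATEGORIES`
order) so runs are reproducible byte for byte. In the per-gene model
fitter, responses that are fitted exactly (constant genes) report zero
effects with $p = 1$ rather than 0/0 noise ratios.

## The simulator

`make_profiles()` draws linear-scale baseline expression per gene from a
log-normal distribution (meanlog 5, sdlog 1 — typical linear intensities of
a few hundred with a long right tail) and gives each cell type a disjoint
block of marker genes enriched `fold` times over baseline in their own
type. `simulate_mixture()` mixes the type profiles **linearly** — physical
mixtures of cells combine transcripts linearly — and observes
$\log_2(x + 1)$ plus additive Gaussian noise on the log2 scale, the
standard array error model. `simulate_cohort()` adds subject covariates
(pH, agonal factor, PMI, age, sex, diagnosis, batch) with per-sample
cell-type proportions given by a softmax over per-type log-odds:
covariate effects enter as log-odds shifts, which keeps proportions on the
simplex under arbitrary effect sizes. A per-sample log-odds jitter
(sd 0.3) provides biological composition variability that is independent
of every covariate, so null cohorts still contain realistic composition
variation rather than pure measurement noise.

Study conditions used by the validation experiments (fixed as defaults in
the `*_experiment` helpers): 200 genes, 10 cell types with 8 markers each,
8-fold marker enrichment, two reference publications per type, expression
noise sd 0.3, cohorts of 150–200 samples, 100–500 replicates per
experiment. These sizes keep every experiment comfortably reproducible on
a laptop while leaving Monte-Carlo error well below the decision margins.

What the simulator does **not** emulate: probe cross-hybridization,
3'-bias and RNA-degradation curves, platform batch artifacts, count noise
of RNA-Seq, correlated marker co-expression beyond shared composition, or
markers of graded specificity (every simulated marker is equally and
perfectly specific). Passing the validation experiments therefore shows
the algorithm is implemented correctly and behaves as designed under its
own assumptions — not that real tissue satisfies those assumptions.

## What the validation experiments show

* **Oracle agreement.** The full pipeline agrees with an independent
  naive-loop reimplementation to $10^{-10}$ on random matrices, including
  multi-probe collapse and cross-category filtering.
* **Pure-sample recovery.** With one pure sample per type, the largest
  consolidated index identifies the true type, noiselessly and under
  log2-scale noise of sd 0.5.
* **Titrations.** On noiseless two-type titrations (proportions 0–1 in
  steps of 0.25) every index is strictly monotone in its own type's
  proportion (Spearman $\rho = 1$). Exact linearity is *not* achievable
  under these conditions, and the deviation has a closed form: with all of
  a type's markers enriched 8-fold, every marker row observes
  $\log_2(b(1 + 7p) + 1)$, all z-scored marker rows are identical, and
  $R^2(\text{index}, p) = \mathrm{cor}(p, \log_2(1+7p))^2 \approx 0.917$.
  The log curvature grows with the enrichment factor ($R^2 \ge 0.95$ would
  require roughly 5-fold enrichment or weaker), so we report the exact
  0.917 rather than weakening the enrichment to manufacture linearity;
  with realistic mixtures of many types and heterogeneous folds the
  relationship is closer to linear, which is what was observed on real
  admixture data.
* **Type-I control.** Scanning indices against covariates on null cohorts
  yields ~5% of nominal $p < 0.05$.
* **Effect recovery.** A simulated astrocyte decrease with depression
  (log-odds shift $-0.5$, $n = 150$) is recovered in sign essentially
  always across 200 cohorts.
* **Mediation.** When a diagnosis effect is purely compositional, the
  affected markers' diagnosis coefficients attenuate once the prevalent
  cell-type indices enter the model, and per-gene centered BIC over those
  composition-driven genes favors the index-adjusted model. Averaged over
  *all* genes the picture reverses — five extra covariates cannot pay
  their information-criterion penalty on genes unrelated to composition —
  which is exactly why index covariates are recommended only for datasets
  with substantial composition variability.

## Downstream statistics

`index_covariate_scan()` fits one OLS model per index with all covariates
entered **simultaneously** (each coefficient is adjusted for the others;
marginal per-covariate models would confound, e.g., agonal state with
diagnosis). Three presets mirror the covariate sets available for
post-mortem cohorts; categorical terms are treatment-coded with declared
references (diagnosis `CTRL`, sex `F`), and listwise deletion is applied
per model with the used $n$ reported. `meta_analyze()` pools scans across
datasets by fixed-effects inverse-variance weighting with normal-theory
inference ($z = \hat b/\mathrm{SE}$) — the standard choice when a single
common effect is assumed — and BH-adjusts q-values over the entire pooled
family of cell types $\times$ covariates, not per covariate.

`fit_de_models()` compares five nested per-gene specifications: diagnosis
only (M1), plus traditional covariates (M2), plus the five prevalent
cell-type indices without (M3) or with (M4) traditional covariates, and
all ten indices (M5). All five are fitted on one shared listwise-complete
sample set so AIC/BIC (full Gaussian log-likelihood, constants included,
residual variance counted as a parameter) are comparable. Diagnosis is one
multi-level factor with per-level extraction. Plain OLS is used
throughout; moderated (empirical-Bayes) statistics are deliberately out of
scope, and results for very small cohorts should be read accordingly.
Replication against a prior-effect reference list uses the documented
direction and nominal $p < 0.05$ (not q) as the detection criterion, and
Fisher's exact test (two-sided by probability mass, the conventional
definition) compares detection rates and set enrichments between models.

Cohen's d uses the classic pooled sd,
$s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$ — the convention
must be fixed because the average-sd variant differs for unbalanced
groups; the classic form is the default meaning of "pooled" in the
behavioural literature.

## A worked example

```{r example}
profs <- make_profiles(seed = 1)
db    <- make_synthetic_db(profs, pubs_per_type = 2, seed = 1)
co    <- simulate_cohort(profs, n_samples = 150,
                         effects = list(diagnosisMDD = c(Astrocyte = -0.5)),
                         seed = 2)
ix <- cell_type_indices(co$expr, db)
ix
summary(ix)

scan <- index_covariate_scan(ix, co$metadata, model = "eq1", dataset = "sim")
subset(scan, covariate == "diagnosisMDD" & cell_type == "Astrocyte")
```

## The full-scale synthetic reference database

`synthetic_reference_db()` deterministically generates a marker table with
the documented *shape* of a full curated cortical marker resource — 38
publication-specific sets from 8 source studies across the 10 categories,
3383 assignment rows over 2499 unique symbols, a 17-gene erythrocyte set,
12 cross-category genes — but with placeholder gene symbols. It exists to
exercise loading, set derivation and export at realistic scale; it
carries no biology and must never be used for real analyses.

## Known limitations

* Indices are relative within a dataset; values are not comparable across
  datasets, and cross-dataset synthesis should pool model coefficients
  (as `meta_analyze()` does), never raw indices.
* Composition and cell-intrinsic transcriptional activity are
  fundamentally confounded in a single index.
* The gene-collapse and min-genes rules assume reasonably complete gene
  annotation; sparsely annotated platforms will silently shrink coverage
  (reported in the `coverage` field — check it).
* OLS per gene assumes roughly Gaussian residuals on the log scale; counts
  should be transformed and normalized upstream.
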