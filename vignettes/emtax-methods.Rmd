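---
title: "Quantifying EMT programs and states with emtax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMT programs and states with emtax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtax)
```

## The problem

Epithelial–mesenchymal transition (EMT) is a continuum: cells lose
epithelial (E) identity and gain mesenchymal (M) traits, often passing
through hybrid intermediate states, and different lineages can activate
*different* mesenchymal gene programs. Quantifying where each bulk sample
or single cell sits on this continuum is usually done by scoring the
activity of an E gene set and an M gene set in each sample. emtax
implements a suite of such scorers, plus downstream machinery for three
questions a single E/M score pair cannot answer:

1. Are there **divergent mesenchymal programs** — disjoint subsets of M
   genes upregulated in disjoint subsets of samples?
2. Which samples form **extreme-E, extreme-M and hybrid subpopulations**,
   relative to this dataset?
3. Which other gene sets (pathways, processes) **co-vary with EMT
   progression** across the dataset?

## Input contract and normalization

Expression is ingested as a genes × samples matrix: either a dense TSV/CSV
(gene ids in the first column) or a MatrixMarket triplet
(`matrix.mtx` + gene/sample id files). Gene-symbol matching is
case-insensitive everywhere (GMT files and matrices routinely disagree in
case). Raw counts are normalized per sample to counts-per-10,000 followed
by `log1p`; this is the common single-cell convention and puts all five
scorers on a single input contract. Matrices normalized upstream can be
ingested with `normalized = "lognorm"`, which skips this step. The
packaged `E`/`M` marker sets (`builtin_em_genesets()`) are a small curated
convenience list of canonical EMT markers so that the pipeline runs out of
the box; any serious analysis should substitute the user's preferred
published E/M gene sets via GMT.

## The five scorers

All scorers return per-sample scores; only nonnegative PCA returns
multiple ranked axes with gene loadings.

**Nonnegative PCA (default).** The gene-set submatrix is centered per gene
and the covariance `S` of its genes is attacked with projected power
iteration: iterate `v <- S v`, clip negative entries to zero, renormalize,
until the update moves less than `tol = 1e-6` (max 500 iterations, with a
recorded warning and the best iterate on non-convergence). The iterate is
initialized from the absolute value of the leading eigenvector of the
current covariance; if it collapses to zero, up to 5 seeded random
nonnegative restarts are tried. Each component's achieved variance
`lambda = v'Sv` is recorded and the covariance deflated by
`S - lambda v v'` before the next component. Properties that follow:
loadings are nonnegative with unit norm, per-axis scores are zero-mean,
achieved variances rank the axes, and whenever the unconstrained leading
eigenvector is already nonnegative (e.g. all-positive covariance) the
result coincides with standard PCA. Because nonnegativity and
orthogonality conflict, successive components are *not* orthogonal; the
deflation is the standard rank-one subtraction. Scoring an E set and an M
set together yields axes `E, M1, ..., Mk` (default `k = 2` mesenchymal
components, 1 epithelial component).

**ssGSEA.** Per sample, genes are ranked by expression and the enrichment
score is the sum of running differences between the weighted in-set
empirical CDF (weights = rank value to the power `alpha = 0.25`) and the
unweighted out-of-set CDF — a Kolmogorov–Smirnov-style running-sum
statistic. We use the sum-of-differences form (not the maximum deviation)
and expose no per-sample significance test: only the enrichment score is
an output of this implementation.

**AUCell-style.** Per sample, the score is the area under the curve
counting set genes among the top `r` ranked genes for `r` up to
`ceiling(0.05 * n_genes)`, normalized by the maximal achievable area, so
scores lie in [0, 1]. Ties in the ranking are broken deterministically by
case-folded gene id (reproducibility over randomized tie-breaks).

**SCSE.** The summed expression of the set genes as a percentage of the
sample's total expression; invariant under per-sample rescaling.

**JASMINE-style.** The mean of two min–max-scaled components: the mean
rank of *expressed* (value > 0) set genes among expressed genes divided by
the number of expressed genes, and a dropout-aware odds ratio of set genes
being expressed versus non-set genes being expressed, with a 0.5
continuity correction. A sample with no expressed set gene contributes a
rank component of 0; a component constant across samples scales to 0 by
convention.

Default minimum set/matrix overlap is 5 genes for the variance- and
distribution-based scorers (nnPCA, ssGSEA, JASMINE) and 1 for the simple
sum/recovery scorers (SCSE, AUCell); zero-variance genes are dropped from
the nnPCA submatrix and recorded in `genes_used`.

Whether genes should also be scaled to unit variance before nnPCA is a
genuinely open choice; the default is center-only (gene variance is part
of the signal the component ranks), with `scale = TRUE` available.

## Divergent programs

With two mesenchymal axes, `top_contributing_genes()` lists the top-k
loading genes per axis (ties broken by gene id), and `divergence_index()`
contrasts each gene's loadings: `(w1 - w2) / (w1 + w2 + 1e-12)` in
[-1, 1], where ±1 marks pure single-axis contributors and the epsilon
guards genes with zero loading on both axes. `assign_branches()`
formalizes the visual reading of an M1–M2 scatter: both axes are z-scored
and a sample is branch-dominant when it reaches the 0.75 quantile on one
axis and exceeds its score on the other; everything else is unpolarized.
The quantile rule is this package's own formalization — the underlying
analysis practice is visual inspection of the scatter — and 0.75 balances
calling enough polarized samples against contaminating the calls with
axis noise. There is deliberately no statistical test that two programs
"exist"; the ranked variance-explained table and the scatter output are
the evidence presented to the user.

## EMT states

`fit_gmm()` clusters samples in the 2-D (E score, M score) plane with a
full-covariance Gaussian mixture fitted by EM (own implementation: the
contract requires seeded restarts, a per-fit log-likelihood trace for the
monotonicity invariant, and bit-reproducibility; `mclust` serves as an
independent cross-check in the test suite). For each candidate `k` in
2..6, 5 seeded k-means-initialized restarts are run and the best kept;
the returned `k` minimizes `BIC = -2 logL + (6k - 1) log n` (2 means + 3
covariance entries per component, k−1 free weights). Covariances carry a
small diagonal ridge (1e-6 of the data variance) to avoid degeneracy;
degenerate restarts are discarded and an error raised only if all
restarts fail. `label_states()` then z-scores both axes and computes each
cluster's polarity `delta = mean z(M) - mean z(E)` over its hard-assigned
samples: the minimum is the extreme-E state, the maximum the extreme-M
state, everything between is `hybrid-i` ordered by mean M score (ties in
delta broken by mean M; an empty hard cluster falls back to its model
mean; `k = 1` is labeled `hybrid-1`). The z-scoring makes the rule
scale-free across scoring methods, and up to `k - 2` hybrid states are
allowed — the number of hybrids is a property of the fitted mixture, not
a cap.

`crosstab_states()` builds the label × state contingency table behind a
Sankey diagram (counts, row proportions, and a flow list sorted by
count). `trend_over_pseudotime()` summarizes scores along an externally
inferred pseudotime using equal-count quantile bins (default 20) — a
deterministic, parameter-light alternative to a smoother. Pseudotime is
consumed from metadata only; this package never infers trajectories.

## Screening gene-set collections

`screen_genesets()` scores every set of a GMT collection (for nnPCA, the
leading component per set — the default reference is likewise the leading
mesenchymal score M1) and reports the Pearson correlation of each set's
scores with the reference across samples, with two-sided p-values from
the t-distribution (n−2 df) and Benjamini–Hochberg q-values across all
tested sets. The correlation coefficients are the primary output; the
q-values are an auxiliary multiplicity guard. Sets with too few matched
genes or constant scores are listed as skipped with machine-readable
reasons (`low_overlap`, `constant_score`), never silently dropped, so
tested + skipped always equals the collection size. `top_hits()` returns
the top positive and top negative lists separately, bar-chart ready. For
large collections `method = "scse"` screens thousands of sets against
thousands of samples in seconds on one CPU; Spearman correlation is
available behind a flag.

## The synthetic-data generator

`simulate_expression()` plants known structure so every downstream claim
can be checked against ground truth without any external download.
Per-gene baseline log-means are drawn from Normal(1.5, 0.5); a latent EMT
position `u` in [0, 1] shifts E genes' log-means by `-effect_size * u`
and M genes' by `+effect_size * u` (default effect 2.0 on the natural-log
scale, a strong induction). Counts are negative-binomial (dispersion
`size = 2`), zero-inflated at rate 0.3 in single-cell mode (bulk mode
sets dropout to 0). Latent designs: uniform (`continuous_uniform`),
three well-separated subpopulations at 0.05/0.5/0.95 with sd 0.03
(`three_state`), and four ordered time labels with latent means
0.1/0.35/0.65/0.9, sd 0.05 (`time_course`; the sd is our choice —
tight enough to keep labels ordered, loose enough to overlap adjacent
time points as real inductions do). With a second divergent program
(`n_m2_genes > 0`), samples are split into two branches and each M
program is upregulated only in its branch — mutual exclusivity is the
defining feature of divergence. Pseudotime is the latent position plus
Normal(0, 0.05) noise, standing in for an externally inferred trajectory.
A fixed seed makes the output bit-identical.

What the generator does *not* emulate: real gene–gene correlation
structure, batch effects, mean-variance trends of specific platforms, or
expression-level-dependent dropout. Passing tests on this generator
therefore demonstrate that the estimators recover the structure they
target under controlled noise, not that any particular biological dataset
contains such structure.

## Validation design and problem sizes

The packaged validation (`scripts/acceptance.R`, mirrored in the test
suite) uses two regimes deliberately:

- **Bulk mode** (no dropout) for parameter recovery, divergent-program
  detection, three-state detection and the collection screen — emulating
  a bulk expression panel of cell lines, and matching the generator's
  contract that the three-state design yields *well-separated*
  subpopulations in score space. Sizes: 500 samples × 1,000 genes
  (recovery, divergence, states), 2,000 samples × 1,000 sets (screen).
- **Single-cell mode** (dropout 0.3) for the time-course state-proportion
  and pseudotime-trend checks — emulating an scRNA-seq induction
  experiment, where rank/proportion summaries are robust to dropout.

Under single-cell dropout, per-sample recovery of the latent axis by any
linear combination of the 50 planted M genes is noise-limited to a
Pearson r of about 0.85 (the mean-expression oracle itself achieves no
more); bulk mode removes that ceiling. This is a property of the noise
model, worth knowing when interpreting absolute score–covariate
correlations on sparse single-cell data.

## Numerical and degenerate-input conventions

- Rank ties: average ranks for ssGSEA and JASMINE; deterministic
  id-based tie-break for AUCell's discrete curve.
- An all-zero sample column is an error at normalization (named sample).
- A gene set covering *all* matrix genes is a degenerate ssGSEA input
  (empty complement) and an error.
- nnPCA non-convergence is a recorded warning, not an error; an iterate
  collapsing to zero triggers seeded restarts and errors only if all
  collapse.
- GMM needs at least 20 samples and 5 per candidate component.
- More pseudotime bins than distinct pseudotime values is an error.

## Known limitations

- nnPCA components are not orthogonal (deflation under a nonnegativity
  constraint); variance explained is per-component achieved variance, and
  axis order between near-equal components can depend on noise — on
  divergent data, which planted branch lands on M1 versus M2 is
  arbitrary.
- The branch rule and the extreme-state rule are dataset-relative
  (z-scored); they are not calibrated absolute thresholds.
- The screen's p-values assume independent Gaussian-ish scores; with
  strongly dependent sets they are heuristic — hence coefficients first.
- No per-sample enrichment significance is produced for any scorer.
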