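---
title: "Methods: promiscuity-corrected metabolic enrichment and rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promiscuity-corrected metabolic enrichment and rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`metrewire`, the parameters that matter, the numerical choices we made
where the design was genuinely open, and what the synthetic-data tests do
and do not establish about real data.

## Differential expression

### Negative-binomial Wald test

Counts are modelled per gene as NB with `variance = μ + α μ²`, log link,
design `~ 1 + group`, and per-sample offsets `log s_j`, where the size
factors `s_j` are median-of-ratios: the median over genes (restricted to
genes with a positive geometric mean, i.e. expressed in every sample) of
`count_gj / geomean_g`. If no gene is expressed in every sample the
estimator has no reference and we raise an error rather than silently
switching to a pseudo-reference; the error message names that fallback so
the caller can filter samples deliberately.

Fitting is iteratively reweighted least squares, vectorized across genes
(the two-parameter design reduces the normal equations to a closed-form
2×2 solve per gene). Coefficients are clamped to ±50 on the natural-log
scale to keep degenerate genes (a group with all-zero counts) finite;
convergence tolerance is 1e-10 on the coefficients, at most 50 iterations.

Dispersion estimation follows the moderation scheme standard for this
model class:

1. **Gene-wise ML**, Cox–Reid adjusted (`-½ log det(XᵀWX)`), optimized in
   log-dispersion over `[1e-8, 30]` with the mean held at the current fit
   (the usual profile approximation), with one refit of the means in
   between.
2. **Parametric trend** `α(μ) = a0 + a1/μ`, an iteratively
   outlier-trimmed Gamma GLM (genes whose ratio to the current trend
   falls outside `[1e-4, 15]` are dropped, up to ten refits). The fit is
   rejected if the asymptotic dispersion `a0` is non-positive; a negative
   `a1` is clamped to zero.
3. **MAP shrinkage**: posterior mode under a log-normal prior centred on
   the trend, prior variance
   `max(mad(log residuals)² − trigamma((n − p)/2), 0.25)`. Genes more
   than two prior SDs *above* the trend are left at their gene-wise
   estimate — shrinking true outliers would anticonservatively narrow
   their Wald statistics.

The Wald statistic is `β̂/SE(β̂)` with a two-sided standard-normal
p-value and BH adjustment across testable genes; all-zero genes are `NA`
and excluded from the BH family. We deliberately do **no** independent
filtering and no fold-change shrinkage: the signed Wald statistics are
consumed downstream as a ranking, and shrinkage would distort the ranking
scale that the promiscuity correction divides.

A note on an approximate invariance: multiplying one sample's counts by
`c` multiplies its size factor by `c^{(n−1)/n}` (the geometric-mean
reference moves too) and leaves the Wald statistics *almost* unchanged —
the NB likelihood genuinely sees the rescaled counts, so the invariance
is approximate rather than exact. The test suite checks tight coupling
(correlation > 0.999) rather than bitwise equality.

### t-test path

For continuous expression matrices the per-gene test is a Welch
(unequal-variance) two-sided t-test. The description of the procedure we
follow says "Student's t-test" without specifying variance pooling; we
chose Welch because equal group variances are not plausible for
tumor-vs-normal comparisons and the Welch test is the safer default.
Shapiro–Wilk is run on the within-group-centred residuals and its p-value
exported as a QC column; genes are *not* dropped when normality is
rejected — the procedure we implement runs the t-test regardless, and
transparency about the normality evidence is the useful middle ground.

## Promiscuity correction and GSEA

Promiscuity `m_g` is the number of signature pathways containing gene
`g`; the correction divides the signed statistic by `m_g`. Genes present
in the expression data but absent from the signature are excluded from
the GSEA universe (the analysis concerns metabolic genes only; the
dropped count is logged). Identifier matching is exact string match after
whitespace trimming — alias resolution is data curation, out of scope.

The enrichment score is the weighted Kolmogorov–Smirnov-like running sum:
walking down the ranking, hits increment by `|z|^p / Σ_hits |z|^p` and
misses decrement by `1/(N − N_h)`; ES is the maximal signed deviation.
Defaults: weight `p = 1` (classic weighted GSEA; configurable over
{0, 1, 1.5, 2}), set-size bounds 5–500, 1000 permutations. The running
sum is piecewise linear between hits, so both extremes are found in
O(set size) from the hit positions alone; the test suite checks this
against a naive full-walk implementation and against an independent
implementation of the same statistic.

The null is built by permuting **gene labels** of the statistic vector —
the pipeline receives statistics, not expression, so sample permutation
is not available — and all pathways share the same permutations, which
makes p-values comparable across sets. Directional p-values use the
plus-one estimator, `p_up = (1 + #{ES* ≥ ES}) / (B + 1)`, so no p-value
is ever zero, and BH runs within each direction. Ties in the statistic
are broken by lexicographic gene identifier, and permutations act on
gene identities in a canonical (lexicographic) gene order; together these
make results independent of input order and give an exact sign-flip
symmetry (negating all statistics swaps `p_up` and `p_down` for the same
seed) whenever the statistics are tie-free.

`n_perm ≥ 100` is enforced: below that the permutation tail is too
unstable to BH-adjust meaningfully. Note the granularity interaction
between `n_perm` and the number of pathways: with `B` permutations the
smallest attainable q-value is about `P/(B+1)` for `P` pathways, so
calling significance at FDR 0.05 over a 60-pathway signature needs
`B ≥ ~1200` in the worst case; the default 1000 is adequate because
planted effects occupy the extreme tail jointly.

## Tissue rewiring scores

The variance-stabilizing transform is the closed-form antiderivative of
`1/√v(q)` for the NB variance on the normalized-count scale,
`v(q) = q(1 + a1) + a0 q²`:

```
f(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0))
```

with `(a0, a1)` from the same parametric trend machinery as the Wald
stage (intercept-only fits). It is monotone in the counts, ~log2 for
large counts, and ~2√q as the dispersion vanishes. If the trend fit fails
the transform falls back to `log2(normalized + 1)` with a prominent
warning and provenance tag `"shifted-log"`. A pre-fitted trend can be
passed explicitly, which makes the transform a pure function of the
normalized counts (used by the invariance tests, and useful when two
compartments should share a scale). Normal and cancer compartments are
transformed **independently**, per the procedure this package implements.

The scores are computed literally as ratios of VST-scale means: per-gene
per-tissue means `x̄_{i,t}`, fold change `r_{i,t} = x̄_{i,t} /
mean_t(x̄_{i,t})` (unweighted mean over tissues, focal tissue included),
pathway score `S_{p,t}` = mean of `r` over the pathway's measurable
genes. We implement the ratio as printed even though the VST scale is
log-like; the row-mean identity `mean_t r_{i,t} = 1` holds exactly and is
tested to 1e-12. Genes with a zero cross-tissue average are flagged `NA`
and excluded downstream with a log entry.

Classification crosses the per-tissue enrichment direction of each
pathway in normal tissue (GSEA of the tissue vs the pooled other tissues)
with its direction in the matched cancer (GSEA of cancer vs its normal):
normal-up & cancer-down → **lost**; normal-down & cancer-up → **gained**;
otherwise significant in normal → **maintained**; not significant in
normal → **unchanged**. Only the lost/maintained corners were pinned down
by the rule-table we follow; this completion is ours and makes the
fractions sum to one within each normal-status stratum. The
tissue-independent summary counts pathways moving up/down in more than
20% of cancers regardless of normal status.

## Survival stratification

Observed time is `days_to_death/365.25` for the deceased (death time is
authoritative if both fields are present) and
`days_to_last_followup/365.25` otherwise. The threshold is the 75th
percentile of **all patients' observed times** — not 0.75 × maximum
follow-up; the type-7 linear-interpolation quantile is the default and
configurable, since the exact convention used upstream is not stated.
Strict inequalities put a patient sitting exactly on the threshold in
neither group (excluded with reason `boundary`); other exclusion reasons
are `alive-short-followup`, `dead-late`, `missing-status`,
`missing-time`. Cohorts with fewer than five patients in either group are
dropped.

## Clustering and essentiality

PAM runs on Euclidean distances over per-sample pathway means, unscaled
by default (`scale = TRUE` z-scores first); BUILD initialization plus
SWAP makes it deterministic up to distance ties, which the underlying
implementation breaks by lowest index. The gap statistic uses the
simplest Tibshirani reference — uniform over each feature's observed
range (zero-range features are dropped from reference generation) — with
`B = 50` draws by default and the 1-SE rule (smallest `k` with
`Gap(k) ≥ Gap(k+1) − SE(k+1)`). Cluster labels are arbitrary; tests
compare partitions label-freely. Tissue enrichment is the upper-tail
hypergeometric probability per (cluster, type) with BH over all pairs at
FDR 0.05.

Essentiality scores follow the ATARIS convention (lower = more
essential); a `higher_is_essential` flag negates other screens into this
convention on input. The top 5% is computed per cell line over its
non-NA genes, `floor(0.05 · n_scored)` genes, boundary ties broken by
gene identifier. Tissue sets are **unions** over a tissue's cell lines;
occurrence is the number of tissues whose set contains the gene, and the
pathway value is the mean occurrence over the pathway's genes present in
the scored universe.

## Correlation analyses

All correlations are Spearman (midrank Pearson) with the large-sample
t approximation for p-values and BH within each call family. The
OXPHOS-vs-EMT analysis computes, per cohort, per-patient median OXPHOS
and median EMT expression restricted to the high/low-survival patients
and correlates the two across patients. The alternative reading — one
point per survival group, two points per cohort — is degenerate for a
correlation coefficient, which is why we correlate across patients; the
group labels only select which patients enter, so swapping them changes
nothing.

## The synthetic-data generator

`simulation_config()` defaults describe the study conditions the tests
run under: 2000 genes, 60 pathways, 80% of genes in the signature, 20%
of signature genes promiscuous (placed in one or two extra pathways),
20 + 20 samples per tissue, log-normal baseline means
(`meanlog = log 100`, `sdlog = 1.2`), dispersion trend
`α(μ) = 0.05 + 2/μ` with log-normal noise (SD 0.3), library-size factors
log-normal (SD 0.15), and four planted pathway effects (two up, two
down, |log2FC| = 1.5). These magnitudes are typical of bulk RNA-seq
cohorts of this size and make a full simulate → DE → GSEA round run in
seconds. Clinical tables designate 25% high-survival patients (censored
alive uniform 9–10 y), 35% low-survival (death times exponential, mean
1.5 y) and 40% background (censored 0.5–7 y), which places the 75th
percentile of observed times between the background and high blocks so
the stratification rule can recover the designated groups. Essentiality
matrices plant a 3-SD downward shift for 30 genes in one tissue (5
tissues × 10 lines).

What the generator does **not** emulate: gene-length and GC biases,
batch effects, correlated genes within pathways beyond the planted mean
shifts, non-NB overdispersion (e.g. zero inflation), informative
censoring, and real promiscuity topology (it plants random extra
memberships rather than the hub structure of a metabolic network).
Passing tests therefore demonstrate correctness of the statistical
machinery under its own model assumptions, not robustness to the
artefacts of real TCGA/screen data. In particular, headline counts from
the original pan-cancer study (e.g. the number of clusters found on the
real pooled cohort) require the full external downloads and are out of
desk-scale reach by design.

## Problem sizes used by tests and the acceptance script

Property tests use 100-gene/5-tissue rewiring fixtures, 2000-gene null
and recovery simulations for the Wald stage (n = 10+10 and 20+20), a
380-gene/14-pathway promiscuity scenario over 50 seeds, 200 GSEA null
datasets with 499 permutations, 1000 random clinical tables, 50 seeds
each for gap-statistic recovery of k ∈ {1, 3} (B = 20), and 5–10
essentiality simulations; these sizes give stable pass/fail behaviour at
the stated thresholds while keeping the full suite in the low minutes on
one CPU.

## Known limitations

- The Wald test inherits the small-sample anticonservativeness of all
  plug-in dispersion GLM tests; the moderation scheme keeps the null
  type-I error near nominal at the tested sizes but very small groups
  (< 5 per arm) should be interpreted cautiously.
- Median-of-ratios normalization assumes most genes unchanged; the
  simulated recovery of a planted log2FC of 1 on 5% of genes shows the
  expected slight compression from reference shift.
- The permutation GSEA p-value floor is `1/(B+1)`; q-values saturate
  accordingly for large signatures with small `B`.
- `mixed-directional` enrichment classes, leading-edge reporting,
  Cox/Kaplan–Meier survival modelling, consensus clustering and
  shRNA-to-gene deconvolution are out of scope.
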