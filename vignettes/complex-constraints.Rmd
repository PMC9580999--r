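---
title: "Methods: complex organization and proteome dysregulation"
author: "coabundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex organization and proteome dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coabundance)
```

## The question and the model

Multiprotein complexes need their subunits in the right relative amounts.
When a tumor proteome shifts the abundance of one subunit and not its
partners, the complex either loses function or accumulates orphan subunits.
`coabundance` quantifies the footprint this constraint leaves in
tumor/normal proteomics data in three steps, and then dissects it by
interaction type.

**Step 1 — dysregulation.** Per protein, tumor and normal abundances are
compared with a two-sided Wilcoxon test; p-values are Bonferroni-corrected
with the number of proteins actually tested; the effect size is the
difference of group medians on the log2 scale. Rank tests make no
distributional assumption beyond exchangeability under the null, which
matters because TMT log-ratios are heavy-tailed and cohort pipelines
differ. The dysregulation call (`|log2FC| > 1`, adjusted `p <= 0.05`) uses
a strict fold-change threshold and an inclusive p threshold; both
directions of the boundary are covered by tests.

**Step 2 — membership association.** Dysregulation × complex membership is
tested with an uncorrected Pearson chi-square on the 2×2 table. Complex
subunits are on average more abundant than other proteins, and abundance
itself predicts detectability and variance, so the association is repeated
against an abundance-matched background: the quantified universe is binned
into equal-frequency abundance bins and every subunit is replaced by a
distinct non-complex protein from its own bin. The background then has the
members' bin histogram *exactly* (a construction invariant, not an
approximation), and any residual association cannot be an abundance
artifact.

**Step 3 — co-abundance.** Spearman correlations across tumor samples are
computed for all pairs of catalog-covered proteins, per cohort, and pooled
across cohorts by concatenation: a pair measured in three cohorts
contributes three values. Averaging within a pair would shrink the pooled
distribution's spread and overstate certainty; concatenation mirrors how
the distributions are compared (rank-sum test between pair groups).

**Interaction types.** Five independent classifications annotate pairs:
parity of chain counts (even means equal counts — the operative criterion
behind 1:1, 2:2, 4:4 — with pairs inconsistent across structures excluded
as `mixed`), co-occurrence Jaccard over the catalog, general versus
context-specific detection across two cell lines (restricted to baits
targeted in both), competitive versus cooperative binding (interface
Jaccard on the best shared partner, threshold 0.1 inclusive), and curated
transient/permanent labels. A pair may carry any combination of labels;
classes are never made mutually exclusive, because each comparison is run
per class.

**Pair regression.** For co-structure pairs, ordinary least squares relates
the two proteins' tumor abundances with the lower-copy protein as the
dependent variable. Under stoichiometric scaling a subunit present in k
copies must move k-fold for every unit move of a single-copy partner, so
the dependent-variable rule converts parity into a testable slope ordering:
pairs generated as `higher = β·lower + ε` yield fitted slopes near `1/β`
with the lower-copy protein dependent, separating even (β = 1) from uneven
(β > 1) pairs. Only slopes whose coefficient is significant (p < 0.05,
strict) enter the comparison, stratified by the sign of the pair's Spearman
correlation; pairs with correlation exactly zero are excluded from both
strata.

## The synthetic-data generator

The generator emits every input the pipeline consumes, with ground truth,
so each stage has a recovery test.

* **Co-regulation** uses one Gaussian latent factor per complex: a member
  loads on its complex factor and keeps unit marginal variance. The loading
  is derived in closed form from the target Spearman correlation: for a
  bivariate Gaussian with Pearson correlation r the population Spearman is
  `(6/π)·asin(r/2)`, so the factor share is `r = 2·sin(π·ρ_s/6)`. We chose
  the analytic inversion over a simulated calibration table because it is
  exact for this model and has no tuning state; the realized mean pair
  correlation at 100 tumor samples lands within ±0.05 of the target (tested
  at overlap 0). Proteins in several complexes split their loading equally
  across factors to keep marginal variance fixed, which *dilutes* their
  pairwise correlations — a deliberate property, exercised separately.
* **Differential effects** are additive on the log2 scale:
  `sign·|N(lfc_mean, lfc_sd)|` added to tumor columns. Selection odds
  depend on membership through `depletion_odds_ratio` (0.5 by default:
  subunits half as likely to be dysregulated), and 90% of effects point
  down by default, matching the strong down-regulation bias typical of
  tumor-versus-normal proteomes.
* **Chain counts**: one structure per complex; even structures give all
  members one shared count (1, 2 or 4), uneven structures give distinct
  counts, so every co-member pair is unambiguous. A configurable fraction
  of complexes emits a second structure of opposite parity to exercise the
  mixed-exclusion rule.
* **Interactome**: each complex contributes a hub (its first member) and
  spoke interactions to the other members. Binding sites on the hub are
  planted so a configured fraction of partner pairs overlap at a chosen
  Jaccard and the rest are disjoint; sites are unique per complex and per
  interaction so no spurious overlap arises through other shared partners.
  Detection and bait flags, and a transient-heavy sprinkling of stability
  labels, complete the table. Ground-truth competition labels are computed
  from the *stored* sets with the same max-over-partners rule the
  definition prescribes, so overlapping complexes cannot desynchronize
  truth and data.

Defaults describe a mid-sized study: 2,000 proteins, 50 complexes of 3–6
subunits covering a fifth of the proteome, 30 tumor and 30 matched normal
samples, within-complex Spearman 0.6 over an uncorrelated background, 10%
dysregulated proteins at odds ratio 0.5, |log2FC| around 2, unit
between-sample noise (log2 scale), no missingness unless requested.

What the generator does **not** emulate: TMT ratio compression, batch
effects, isoform-level quantification, and informative missingness
(missingness is completely at random; the coverage filter only needs MCAR
to be exercised). Passing recovery tests therefore show the estimators are
correct under the declared model, not that real cohorts satisfy it.

## Numerical and policy choices

* **Exactness policy for rank tests**: exact null distribution when both
  groups have ≤ 12 non-missing values and no ties; otherwise the normal
  approximation with tie and continuity correction. Degenerate inputs with
  zero rank variance get p = 1.
* **Paired versus unpaired**: the default Wilcoxon is the unpaired
  rank-sum even when a pairing map exists, consistent with defining log2FC
  as a *group*-median difference and robust to missing partners; a paired
  signed-rank switch is provided.
* **Coverage filter**: "quantified in less than 50% of samples" is applied
  strictly (exactly 50% is kept) and counts tumor and normal samples
  together by default; the sample scope is configurable because cohort
  conventions differ.
* **Duplicate symbols** merge to the per-sample mean over available values;
  a merged cell is missing only when all contributing rows are. This
  maximizes retained data at the cost of averaging over isoforms.
* **Spectral counts** are quantile-normalized to the mean empirical
  distribution (ties averaged across tied ranks, via limma), then
  `log2(x+1)`; the pseudocount handles zero counts, and replicate columns
  are averaged after transformation.
* **Binning for the matched background** uses 10 equal-frequency bins of
  the median normal-sample abundance. Deciles guarantee non-empty bins at
  realistic universe sizes; the summary (tumor/normal/all) and bin count
  are arguments. A bin with more members than non-members is a hard error
  naming the bin rather than a silent relaxation.
* **Chi-square** is uncorrected by default (expected counts in realistic
  uses are far above 5, and the statistic then equals the textbook hand
  formula); a Yates flag exposes the corrected version.
* **Jaccard edge cases**: one empty interface set gives overlap 0
  (cooperative); two empty sets leave the index undefined and raise an
  error.
* **Dependent-variable tie-break**: for even pairs "the first protein" is
  made deterministic as the lexicographically smaller symbol; any fixed
  rule works because even pairs have no copy-number asymmetry.
* **Pair keys** are canonical (lexicographic order), so (A,B) and (B,A)
  address one record everywhere; pairs occurring in several complexes are
  deduplicated before group comparisons.
* **Seeds**: one master seed; every stage derives its own stream via a
  fixed integer hash of a stage tag, so adding a stage never perturbs
  another stage's randomness, and identical config + seed reproduces
  output bundles byte for byte (no timestamps are written).

## Problem sizes used by the test suite

The recovery experiments run at sizes chosen to give stable rates while
keeping the default suite fast: association calibration over 2,000 null
draws (universe 2,000, 400 members, 200 dysregulated), depletion power
over 500 draws at odds ratio 0.5, co-regulation recovery with 50 complexes
of 4 at 100 tumor samples, slope recovery over 200 fits of n = 200, and
differential-abundance sensitivity over 10 cohorts of 1,000 proteins at
30/30 samples with 40 null cohorts. The acceptance script repeats the same
experiments at comparable sizes from a single command-line seed.

## Known limitations

* The interaction classifications consume upstream resources as given:
  interface residues, chain counts and stability labels are inputs, not
  computed from structures here.
* Inputs must be gene-symbol-keyed; identifier mapping (and its
  ambiguities) is out of scope.
* The competition definition is structural overlap, which need not mean
  competition in vivo (localization and expression context can keep
  "competing" proteins apart).
* All-pairs correlation across a whole proteome is quadratic; the default
  restricts pairs to catalog-covered proteins, with a capped, seeded
  subsample of different-complex pairs.
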