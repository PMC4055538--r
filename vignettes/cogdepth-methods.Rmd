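---
title: "Methods: depth-stratified COG profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-stratified COG profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogdepth)
```

This vignette is the package's own account of the statistical procedure
it implements: the model behind each stage, the defaults and why they
were chosen, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The data and the sampling model

The unit of observation is a count: the number of shotgun reads from one
dataset (one site × depth) assigned to one COG (cluster of orthologous
groups of proteins). Libraries differ in depth, so all screens operate
on counts **rarefied to a common depth** — `subsample_counts()` draws
the target number of reads per dataset without replacement (a
multivariate hypergeometric draw per column), which preserves the count
nature of the data instead of rescaling it. We call these equal-depth
counts "normalized abundances"; an optional per-10⁴ scaling
(`normalize_counts(per_10k = TRUE)`) exists for inputs whose depths
cannot be equalized. Rarefaction acts on *assigned* reads: assignment
happens upstream and this package only ever sees its tabular output.

The per-column tests treat the two rarefied libraries being compared as
independent multinomial draws from fixed compositions. That assumption
matters for calibration; see *Limitations*.

## Stage 1 — depth-related COGs per water column

Within one water column with `d` sampled depths, every COG is tested
between every pair of depths (`d = 4` gives 6 pairs): the 2×2 table
(COG reads, remaining reads) × (depth A, depth B) goes into **Fisher's
exact test**, two-sided by the point-probability rule — the p-value sums
the hypergeometric probabilities of all tables with the observed margins
that are no more likely than the observed table (relative slack 1e-7
absorbs floating-point noise in that comparison). A dispersion-free
**conditional binomial** test (condition on the COG total; success
probability = the library-size ratio) is available as `test =
"binomial"`; with equal-depth libraries the two are near-identical, and
neither requires the replicate dispersion estimate a negative-binomial
exact test would need.

All (COG, pair) p-values of one column are Benjamini–Hochberg adjusted
**jointly** — the most conservative granularity consistent with
screening a whole column at once — and a COG is depth-related when any
pair reaches adjusted p ≤ `alpha_depth` (default 0.01). Exhaustive
pairs is deliberately the weakest reading of "differs between at least
two depths" that is well defined.

The per-column sets are intersected across the reference columns
(`intersect_depth_cogs()`); an optional presence rule additionally
requires a nonzero count in at least one dataset of each column. The
intersection of significant sets is the default because it is the
stricter of the two readings; both are exposed.

## Stage 2 — photic/aphotic core sets and the ratio diagnostic

Datasets are labelled photic or aphotic by the light rule: PAR at the
sampling depth at or above `par_fraction` (default 1%) of surface PAR.
When at-depth PAR was not measured it is derived from Beer–Lambert
exponential decay, `PAR(z) = PAR₀·exp(−kz)`, so the photic floor sits at
`ln(100)/k` metres.

On the intersected set, each COG gets **Welch's unequal-variance
t-test** between the two groups (the reference design has n = 12 per
group), BH adjustment, and a cut at adjusted p ≤ `alpha_core`. The
default is 1e-4: the analysis this package operationalizes quotes both
0.05 and 1e-4 for this stage, and only the stricter level reproduces its
core-set sizes, so 1e-4 is the default and the other level is one
argument away — neither is hidden. Direction (photic vs aphotic) is the
larger group mean. COGs constant across all datasets have no Welch
statistic; they are excluded from testing (NA p, not counted in the BH
`m`).

The **ratio diagnostic** for a dataset is
`log2((mean over photic core + c) / (mean over aphotic core + c))` with
pseudocount `c = 0.5` equal-depth counts — a guard against empty aphotic
means on tiny inputs, configurable, irrelevant at realistic depths.
Reference **bands** are mean ± 2·SD of the log₂ ratios of the reference
columns' photic and aphotic datasets. A value inside or beyond its band
on the enriched side is called for that zone; anything between the bands
is `intermediate` — bands indicate enrichment, they are not exclusion
intervals, so a dataset even more photic than the photic band is still
photic. Since linear ratios are quoted in both orientations in this
literature, the per-dataset table reports `ratio_photic_aphotic` and
`ratio_aphotic_photic` explicitly.

## Stage 3 — OMZ COGs and the oxygen threshold

The OMZ column is screened exactly like a reference column; the
photic/aphotic core is then removed from the candidates so light-driven
changes cannot masquerade as oxygen effects. The low-oxygen group is
derived from metadata by `do_umol_kg < low_o2_cutoff` (default
20 µmol/kg; in the reference design this yields exactly the three
deepest OMZ datasets, n = 3 vs 21). Each candidate is tested with the
**exact Wilcoxon rank-sum test**: midranks for ties, and the two-sided
p-value enumerates all C(24,3) = 2024 assignments of the pooled values
(the fraction whose rank sum deviates from the null mean at least as
much as observed). Exact enumeration is used whenever
C(n₁+n₂, n₁) ≤ 10⁶; beyond that a tie-corrected normal approximation is
flagged in the method string. With n = 3 the smallest achievable
two-sided p is 2/2024 ≈ 0.001, so power is intrinsically limited — a
property of the design, not the implementation.

Significant COGs are split into profile groups I/II by cutting their
average-linkage tree (Euclidean distance on Z-scored profiles) at k = 2;
group I is the group with the higher mean abundance in the low-oxygen
datasets. This formalizes what is otherwise read off a heatmap. The
**oxygen threshold** is a change-point estimate: order datasets by
dissolved oxygen, and over every split between distinct oxygen values
compute the standardized mean difference (pooled-SD units) of the
group-I mean abundance; the estimate is the midpoint of the oxygen gap
at the best split. It is labelled an estimate, reported with its
separation statistic, and flagged unconfident below `min_separation`
(default 2 pooled SDs) — a smooth dose-response without a step produces
a small statistic, and the estimate should then not be read as a
threshold. With an oxygen grid this coarse the estimate can only
resolve to a gap midpoint: a switch planted at 11 µmol/kg on the grid
{3.2, 4, 11, 25, …} is reported as 18, the midpoint of the 11–25 gap.

## Clustering and bootstrap support

Datasets are clustered on the intersected COG set after row Z-scoring
(mean 0, n−1 SD 1 per COG): average linkage on Euclidean distances —
unspecified upstream, fixed here by config so trees are reproducible.
Node support resamples **COGs** (features) with replacement, rebuilds
the tree, and reports the percentage of replicates containing each
node's exact dataset set; ties in agglomeration follow `hclust`'s
deterministic lowest-index rule. Trees export to newick with supports
as internal node labels.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the reference study design: 3 reference
columns × 4 depths + 1 OMZ column × 4 depths + 8 single-depth sites
(24 datasets, 12/12 photic/aphotic by the 1% PAR rule); 2000 background
COGs plus 54 photic, 28 aphotic and 18 oxygen markers; marker fold
change 4; oxygen switch at 11 µmol/kg; libraries of 50–60k reads
(subsampling then equalizes at the smallest); per-dataset Dirichlet
perturbation of a log-normal base composition; mixed-layer datasets as
convex mixtures λ·photic + (1−λ)·aphotic; per-read phylum labels with
the photic marker profile concentrated in two phyla and the aphotic
profile spread over ten.

Choices the generator fixes that no upstream source dictates, with the
reasoning:

- **Library size 50–60k.** The smallest collection in the design this
  emulates is not published; 50k assigned reads is a typical
  pyrosequencing-era depth and keeps per-COG counts (~25 background,
  ~100 for "on" markers) in a regime where the exact tests have power.
- **Base abundance log-normal, sdlog 0.25.** Mild heterogeneity keeps
  all planted markers above the detection floor of a 50k library; real
  COG abundance distributions are far heavier-tailed, so real screens
  will miss rare functions — a power statement about the data, not the
  method.
- **Dirichlet concentration 1e5** (per-COG CV ≈ 15% at background
  abundance): site-to-site compositional noise strong enough to matter,
  weak enough that a fold change of 4 remains detectable at n = 12 with
  α = 1e-4. `Inf` disables the perturbation entirely, giving the exact
  multinomial null — that is the setting under which test calibration
  is assessed.
- **Deterministic per-dataset `effect_scale`** (0.85–1.10 on the log
  fold): sites differ systematically in enrichment strength, so
  within-zone ratio spread is dominated by reproducible between-site
  differences rather than sampling noise. This is what makes mean ± 2SD
  bands meaningful for classifying *new* datasets: a band estimated from
  six iid noisy replicates would misclassify out-of-sample datasets at
  the t₅-tail rate regardless of noise level.
- **Mixture weights 0.39 / 0.26 / 0.33** for the three mixed-layer
  datasets: under fold change 4 these reproduce the observed
  aphotic:photic linear ratios (≈1.3, 1.8, 1.5) of the mixed-layer
  communities the design emulates.
- **Hard oxygen switch** rather than a logistic response: it makes
  threshold recovery well-posed; the change-point estimator itself makes
  no smoothness assumption either way.

Not emulated: sequence content (no reads, errors, chimeras or assembly
artefacts — the generator plants *assignments*), genome-resolved
structure and covariance between functionally linked COGs (counts are
conditionally independent given the composition), seasonal or replicate
structure within a site, and taxon–function coupling beyond the
per-class phylum profiles. Passing the recovery tests therefore shows
the screening logic is correct and calibrated under its own sampling
assumptions — not that those assumptions hold for any particular real
dataset.

## Numerical and degenerate-input conventions

- Discrete two-sided p-values use the point-probability rule with
  relative slack 1e-7; p-values are clamped to (0, 1].
- Z scores use the n−1 denominator; constant rows are dropped (or raise
  a degenerate-input error if dropping is disabled).
- Welch on a COG with zero variance in both groups yields NA and is
  excluded from the BH family; both-constant inputs to the scalar
  `welch_t()` are an error.
- A zero COG total in the conditional binomial test carries no
  information: p = 1, flagged in the method string.
- `bh_fdr()` passes NA through without counting it in `m`.
- Set operations (`intersect_depth_cogs()`, `exclude_core()`) return
  sorted vectors, so outputs are order-independent.
- All randomness (simulation, rarefaction, bootstrap) is seeded through
  `withr::with_seed`; a pipeline run derives its stage seeds from one
  `seed` argument and is bit-reproducible.

## Problem sizes used by the test suite

The recovery tests run 20 independent replicates of the full reference
configuration (2100 COGs × 24 datasets, ~50k reads each, 100 bootstrap
replicates for the dendrogram) and 20 effect-free replicates for
calibration; oracle-equivalence tests sweep 10⁴ random tables per exact
test and enumerate all 2024 rank-sum assignments at the 3-vs-21 design.
These sizes make the whole suite run in a few minutes on one core while
keeping the Monte-Carlo margins of the asserted rates comfortable.

## Limitations

- **Overdispersion.** Count-level exact tests compare libraries, not
  biological replicates; under extra-multinomial variation they are
  anticonservative for the *population* question. The package follows
  the count-level procedure faithfully (and verifies its calibration
  under the multinomial model); users with replicated designs should
  treat the per-column screens as enrichment filters, which is how the
  downstream stages use them.
- **Band estimation.** Reference bands come from six datasets per zone;
  ±2 SD from n = 6 is a rough interval and meaningful only when
  between-site spread dominates sampling noise (see `effect_scale`
  above).
- **Threshold resolution.** The change-point estimate cannot be more
  precise than the sampled oxygen grid; report the gap, not just the
  midpoint.
- **Group I/II assignment** below two significant COGs degenerates to a
  single group; the k = 2 cut is forced and can split a homogeneous set.
- The Wilcoxon stage at n = 3 vs 21 cannot reach adjusted significance
  for large candidate sets at strict α; the default α = 0.05 matches the
  design's power.
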