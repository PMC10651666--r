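---
title: "Two-sex muscle-aging concordance: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sex muscle-aging concordance: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoconcord)
```

## The scientific question

Skeletal muscle ages differently in men and women at the transcriptome
level: old-vs-young contrasts typically find *more* differentially
expressed genes (DEGs) in females, yet the genes significant in only one
sex tend to move in the *same direction* in the other sex, just with a
smaller fold change. `myoconcord` operationalizes that comparison: per-sex
differential expression, a four-way DEG partition (shared, male-specific,
female-specific, neither), and concordance statistics on paired log2 fold
changes — the percentage of sign agreement, the Pearson correlation, and
the female-on-male OLS slope `m`, read as a cross-sex magnitude ratio.
A slope near 1 on shared DEGs and attenuated slopes on sex-specific DEGs
(below 1 for male-specific, above 1 for female-specific sets) is the
pattern of direction-conserved, magnitude-modulated regulation.

## Differential expression model

Counts are normalized by median-of-ratios size factors: reference genes are
those with nonzero counts in every sample, each sample's factor is the
median of `count / geometric mean` over reference genes, and factors are
rescaled to geometric mean exactly 1 so that the counting scale is
preserved (the rescaling changes no fold change or p-value; it only pins
the normalization invariant used in the tests).

For one sex with `n_y` young and `n_o` old samples, the per-gene log2 fold
change is `log2((m_o + c)/(m_y + c))` with pseudo-count `c = 0.5` normalized
counts (the paper-silent choice; it bounds the log ratio for genes that
drop to zero in one group without noticeably biasing moderately expressed
genes). The test is a negative-binomial Wald statistic: with NB variance
`mu + phi mu^2`, the dispersion is estimated per gene by pooled method of
moments,

    phi_g = max( sum_g (n_g - 1)(s2_g - m_g) / sum_g (n_g - 1) m_g^2 , 1e-8 ),

summing over the two age groups, so both groups inform a single dispersion
(the `1e-8` floor guards degenerate under-dispersed genes). The group-mean
variance `(m + phi m^2)/n` propagates to the log2 ratio by the delta
method, and the Wald statistic is referred to a **t distribution with
`n_y + n_o - 2` degrees of freedom** rather than the normal: at the study's
group sizes (13 young versus ~27 old) the plug-in variance makes the normal
reference visibly anti-conservative, while the t reference keeps the null
rejection rate at a nominal `alpha` of 0.01 and 0.05 within binomial
sampling error of 10,000 simulated null genes — the property the test suite
checks. Genes with all-zero counts are reported as `log2FC = 0, p = 1`.

DEGs are called on the **raw** p-value at `alpha = 0.01` (`-log10 p > 2`),
matching the convention of the analyses this package reproduces;
Benjamini-Hochberg adjusted p-values are computed and reported but never
used for calls. No covariate adjustment, shrinkage or independent filtering
is attempted — the aim is a transparent, oracle-checkable test, not a
DESeq2 re-implementation.

For sample-level QC, `pca_embed()` runs PCA on centered
`log2(normalized + 1)` values of the top 5,000 genes. "Top regulated" is
ambiguous between variance- and significance-based selection; the default
selects by variance (no DE result needed, the common exploratory choice)
and `selector = "significance"` exposes the other reading.

## Concordance statistics

`concordance_stats()` takes paired per-gene log2FCs (male on x, female on
y). Percent same direction counts pairs with `sign(x) = sign(y)` among
pairs where both are nonzero; zero-log2FC pairs are excluded from the
denominator and reported separately (`n_zero_excluded`) rather than being
assigned a side. The slope `m` is the OLS regression of female on male
**with an intercept**, matching the plotted-regression convention of
correlation panels; both slope and intercept are reported. Two caveats are
inherited deliberately from that convention: OLS slopes attenuate under
noise in x (no errors-in-variables correction), and the regression is
asymmetric — swapping axes gives `m' = R^2 / m`, an identity the tests
assert rather than hide.

Gene-list-restricted concordance (`geneset_concordance()`) matches symbols
case-insensitively, logs unmatched entries without failing, and exposes
three selections — every listed gene, listed DEGs of either sex, or listed
genes significant in exactly one sex — because published gene-set
correlation panels are ambiguous about which genes enter the plot.

## Harmonizing external microarray cohorts

Per-probe tables `(gene, probe, log2FC, p)` are collapsed to genes with a
significant-probes-first rule: if any probe of a gene has `p < alpha`, the
gene's value is the arithmetic mean of `-log10 p` and of log2FC over the
significant probes only; otherwise over all probes; single-probe genes pass
through. The `-log` base is 10 throughout (the `p < 0.01 ⇔ -log p > 2` DEG
rule fixes the base). The collapse is idempotent on gene-level tables, its
modes are sound (a `significant_only` gene has at least one significant
probe, an `all_probes` gene none), and adding a significant probe can only
move a gene toward `significant_only` — all tested as invariants.

When a cohort arrives as a probe-by-sample log2 expression matrix instead,
`probe_de_from_expression()` applies Welch's t-test per probe with the mean
difference as log2FC. How the original cohort statistics were computed is
generally not recoverable; Welch on log2 intensities is the documented,
pluggable default, and exact replication of any given cohort's printed
numbers is not guaranteed.

`cohort_replication()` re-runs the DEG call, partition and per-set
concordance per cohort and adds the female-excess percentage
`100 (n_f - n_m)/n_m`.

## The count simulator

`sim_config()` defines four truth blocks: shared genes carry one signed
log2FC in both sexes; male-block genes have the full effect in males and
`a_m` times it in females (same sign); female-block genes mirror that with
`a_f`; null genes are flat. Defaults (all overridable):

| parameter | default | rationale |
|---|---|---|
| group sizes | 13/28 male, 13/26 female (young/old) | the study design being emulated |
| blocks | 2000 / 700 / 2600 / 7000 | proportions of the shared and sex-specific DEG sets observed in that design |
| `lfc_magnitude_range` | [0.5, 2.0], uniform, random sign | plausible bulk-muscle aging effect sizes; no published effect-size distribution to copy |
| `a_m`, `a_f` | 0.4, 0.52 | the male- and female-specific cross-sex regression slopes observed in the emulated study (0.40 and 1.93 ≈ 1/0.52) |
| `baseline_mean_range` | [20, 2000], log-uniform | moderately-to-well expressed genes, where the Wald approximation is trustworthy |
| `dispersion` | 0.05 | typical bulk RNA-seq biological dispersion for human cohorts |
| size factors | log-uniform [0.7, 1.4] | realistic library-size spread so normalization is non-trivially exercised |

Counts are NB with `Var = mu + phi mu^2` (Poisson at `phi = 0`); the old
group mean of sex s is `baseline × 2^lfc_s × size factor`. Everything is
deterministic given the single config seed (truth from `seed`, counts from
`seed + 1`, so the same truth can underlie count and probe-table fixtures).
The simulator does **not** model GC/length bias, batch effects, correlated
genes, outlier samples or read-level noise — so passing tests demonstrate
that the pipeline recovers the intended structure under idealized NB noise,
not that it is robust to real-data artifacts.

`simulate_probe_table()` emulates a microarray cohort: each gene gets 1-10
probes whose observed log2FC is truth plus Gaussian noise `sd = 0.25`, with
the p-value the exact two-sided tail of the standardized observation —
hence exactly uniform p-values for null genes, giving the collapse and
replication stages a calibrated fixture.

## Synthetic histology and morphometry

`render_section()` builds a centroidal-Voronoi mosaic (uniform seeds, two
Lloyd iterations) inside a disc, with fiber interiors defined by
`d2 - d1 > gap` (distance to the two nearest seeds), which guarantees a
boundary band of at least `gap_px = 2` px between any two fibers and makes
every truth polygon convex. Green carries interior signal for type-1 fibers
(gain 0.8), red the boundary network (gain 0.85), both with Gaussian noise
(`sd = 0.03`) clamped to [0, 1]. The default pixel size is 0.5 µm/px,
recorded with the truth; geometry that would leave any fiber interior under
16 px is rejected as infeasible.

Segmentation thresholds each channel (Otsu by default; fixed values for
batch-constant intensity work), labels 8-connected components, and drops
components under `area_min = 50` px² as noise specks. Fast fibers cannot be
read directly from the red channel — a membrane marker outlines fibers
rather than filling them — so the default `filled_interior` mode
hole-fills the red boundary network, subtracts the boundary to expose all
interiors, and removes interiors claimed by the green mask; the literal
`raw_subtraction` reading (red area minus green area) is exposed as an
alternative.

The minimal Feret diameter is computed by rotating calipers on the convex
hull (the minimal width is always flush with a hull edge). Pixel masks are
measured over pixel *squares* (hull of the four corners of each hull
pixel), not centers, so an axis-aligned square of side s px measures
exactly s and discretization error stays below one pixel. Collinear inputs
return width 0 flagged `degenerate`. Section summaries report per-type
counts, the type-1 percentage, per-type mean minimal Feret and a 5-µm size
histogram, and fail QC below 70 fibers.

## Numerical choices and degenerate inputs

* p-values are clamped to `[.Machine$double.xmin, 1]`; `-log10 p` is then
  always finite.
* Ranked significance profiles sort by the average of male and female
  `-log10 p`, ties broken lexicographically by gene ID (deterministic
  output ordering).
* `concordance_stats()` refuses n < 2, non-finite values and zero variance
  in x; `pct_upregulated()` flags (warns, returns `NA`) a set with no DEGs
  rather than erroring, since empty intersections are routine with short
  gene lists.
* Partition requires identical gene universes and reports the symmetric
  difference size on mismatch.
* All randomness flows through explicit seeds; no function touches the
  caller's RNG state.

## Problem sizes used by the tests

The suite exercises the full study-sized design (12,300 genes × 80
samples) where the claim demands it — type-I calibration on 10,000 null
genes, 25-replicate runs for the concordance and female-excess checks, and
25 rendered 300-fiber sections for morphometry recovery — and scales down
to a few hundred genes and 6-10 samples per group for structural unit
tests. These sizes keep every property at comfortable statistical power
while the whole suite runs in a few minutes on a single core.

## Known limitations

* The DE test is asymptotic per gene with moment dispersion; it does not
  share information across genes, so it is less powerful than shrinkage
  estimators at very small n and not intended for n < ~5 per group.
* OLS slopes are attenuation-biased under noisy male log2FCs; interpret
  `m` as the plotted-regression convention does, not as an
  errors-in-variables estimate of the true magnitude ratio.
* Probe collapse trusts the supplied gene symbols; no platform annotation
  remapping is performed.
* The section renderer produces convex, gap-separated fibers with uniform
  illumination; segmentation accuracy on it is an upper bound for real
  immunofluorescence with bleed-through, uneven staining or touching
  fibers.
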