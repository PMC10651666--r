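# myoconcord

Sex differences in the aging skeletal-muscle transcriptome are mostly a
matter of *magnitude*, not *direction*: when a gene responds to aging in one
sex, it almost always moves the same way in the other sex, only more or less
strongly. `myoconcord` packages the analysis needed to make and test that
claim — per-sex differential expression of old versus young muscle,
partitioning of differentially expressed genes (DEGs) into shared and
sex-specific sets, and cross-sex direction-of-regulation concordance
statistics — together with a probe-to-gene collapse step for harmonizing
external microarray cohorts and an immunofluorescence fiber-typing /
morphometry toolkit for the matching histology. It is aimed at
transcriptomics and muscle-physiology researchers comparing old-vs-young
contrasts between groups.

## The statistics at the core

For each sex the old-vs-young contrast per gene g is

* `log2FC_g = log2((m_old + c) / (m_young + c))` on median-of-ratios
  normalized counts (pseudo-count `c = 0.5`);
* a two-sided negative-binomial Wald p-value with method-of-moments
  dispersion `phi` in `Var = mu + phi * mu^2`, pooled across age groups;
* the DEG rule is a raw `p < 0.01` (equivalently `-log10 p > 2`).

Genes are partitioned into **shared** (significant in both sexes),
**male-specific**, **female-specific** and **neither**. For any set of genes
the cross-sex concordance of paired log2FC values `(x_g, y_g)` (male on x,
female on y) is summarized by:

* `pct_same_direction = 100 · #{sign(x_g) = sign(y_g)} / #{x_g ≠ 0, y_g ≠ 0}`
  (the Q2+Q3 quadrants of the correlation plot),
* the Pearson correlation `R`,
* the OLS regression `y = a + m·x`, whose slope `m` reads as the female/male
  magnitude ratio, with its two-sided p-value.

External microarray cohorts enter as per-probe `(gene, probe, log2FC, p)`
tables and are collapsed to one row per gene: the mean `-log10 p` and mean
log2FC over the *significant* probes if any probe has `p < 0.01`, otherwise
over all probes.

For histology, type-1 (MYH7-positive) fibers are thresholded in the green
channel, fast fibers are recovered from the dystrophin boundary network of
the red channel by hole filling and subtraction of the slow area, and each
fiber is measured by its **minimal Feret diameter** (rotating calipers on
the convex hull). Sections with fewer than 70 fibers fail QC.

Because the original count data lives in a controlled repository, the
package ships a negative-binomial simulator with known two-sex effect
structure (shared / male-stronger / female-stronger / null gene blocks) and
a synthetic section renderer with per-fiber ground truth, so the whole
pipeline is testable end to end.

## Worked example

```r
library(myoconcord)

cfg <- sim_config(seed = 7)          # study-sized two-sex scenario
sim <- simulate_counts(cfg)
sim$counts
#> count_matrix: 12300 genes x 80 samples
#>          old young
#>   female  26    13
#>   male    28    13

de_m <- de_test(sim$counts, "male")
de_f <- de_test(sim$counts, "female")
summarize_de(de_m)
#>  n_up n_down
#>  2508   2538
summarize_de(de_f)
#>  n_up n_down
#>  2588   2586

part <- partition_degs(de_m, de_f, alpha = 0.01)
part
#> deg_partition (alpha = 0.01):
#>          shared   male_specific female_specific         neither
#>            4787             259             387            6867

shared <- part$shared
concordance_stats(de_m$log2fc[match(shared, de_m$gene)],
                  de_f$log2fc[match(shared, de_f$gene)])
#> concordance_stats: n = 4787 | same direction 100.0% | R = 0.905 | m = 1.069 (p = 0)
```

Reading the output: the simulated scenario has 2,000 genes with identical
true effects in both sexes, 700 male-stronger and 2,600 female-stronger
genes (attenuated in the other sex) and 7,000 nulls, at the study's group
sizes (13/28 young/old males, 13/26 females). The DE step calls roughly
balanced up/down DEG counts per sex; the shared DEGs agree in sign in
essentially 100% of genes with a regression slope near 1 — the signature of
direction-conserved, magnitude-modulated regulation the package is built to
quantify. `run_pipeline()` chains all stages (including optional gene-list
concordance and cohort harmonization) from a YAML config and writes a JSON
report; `render_section()` / `segment_fibers()` / `summarize_section()` do
the same for the histology arm.

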