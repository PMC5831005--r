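---
title: "Methods: differential open chromatin analysis with docseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential open chromatin analysis with docseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docseq)
```

## The problem

Induced pluripotent stem cells remember something of the tissue they came
from: iPSC lines reprogrammed from pancreatic beta cells differentiate
toward endocrine pancreas more readily than lines reprogrammed from skin
fibroblasts, and part of that propensity is visible as residual open
chromatin at regulatory elements of the endodermal programme. docseq
implements the statistical chain used to detect and interpret that
signature from ATAC-seq data: find peaks whose accessibility differs
between the two iPSC groups (differential open chromatin sites, DOCS),
test whether the DOCS concentrate in functional annotations (chromatin
states, transcription-factor binding sites), attach DOCS to genes and
pathways through regulatory domains, and check that the chromatin
differences propagate to gene expression during directed differentiation.

Every stage operates on plain tabular objects — region tibbles
(`chrom`/`start`/`end`, 0-based half-open), count matrices with a sample
sheet, result tibbles — so the whole pipeline composes with dplyr and can
be driven either from R or by `run_pipeline()` with a YAML config.

## The differential model

Counts for peak $i$ in sample $j$ are modelled as negative binomial,

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij} = s_j\, e^{\beta_{0i} + \beta_i x_j},\ \alpha_i\right),
\qquad \mathrm{Var} = \mu + \alpha \mu^2,$$

with $x_j = 1$ for group-A samples, $s_j$ a per-sample size factor
(median-of-ratios, rescaled to geometric mean 1) and $\alpha_i$ the
per-peak dispersion. The two coefficients are fitted per feature by a
Newton iteration on the log-likelihood with $\alpha_i$ held fixed,
vectorised across all features simultaneously; `log2FC` $= \beta_i/\ln 2$
with positive values meaning more accessible in group A. The Wald
statistic $\beta_i/\mathrm{SE}$ (expected information) is referred to the
normal tail, p values are BH-adjusted, and DOCS are called by the compound
rule FDR $< 0.05$ and $|\mathrm{log2FC}| \ge 0.5$ (both thresholds are
arguments; the fold-change inequality is non-strict). Features with
all-zero counts are excluded and reported; a group with all-zero counts is
handled by a 0.5-count continuity floor on the group means so the
estimate stays finite.

### Dispersion: why the default is a trend

The dispersion is the one genuinely delicate choice at this design size
(5 vs 5). A raw per-feature method-of-moments estimate
$\hat\alpha = \max(\alpha_{\min}, (s^2 - \bar m)/\bar m^2)$ has only 8
residual degrees of freedom behind $s^2$; plugging so noisy an $\hat\alpha$
into a normal-tail Wald test makes the null p values markedly
anticonservative, while widening the reference to a $t_8$ restores
calibration at a severe cost in sensitivity. `estimate_dispersion()`
therefore defaults to a mean-dispersion *trend*: features are ordered by
scaled mean and each receives the windowed moment ratio
$\sum(s^2_i - \bar m_i) / \sum \bar m_i^2$ over its ~101 nearest
neighbours. Because $E[s^2] = \bar m + \alpha \bar m^2$, the ratio is an
approximately unbiased, low-noise estimate of the local dispersion, and
the normal Wald reference is then both calibrated (on a 10,000-peak null
study at $\alpha = 0.1$, depth ~50, the raw p values pass a KS
uniformity test and zero DOCS are called) and powerful (sensitivity
$\approx 0.93$ at planted $|\mathrm{log2FC}| = 1.5$, observed FDP
$\approx 0.05$). Two alternatives are kept: `method = "mom"` (the raw
per-feature estimator) and `method = "eb"`, which shrinks log per-feature
estimates toward the log trend with weights from the delta-method
sampling variance — the appropriate middle ground when true dispersions
vary feature-to-feature beyond any mean trend. When a grouping is known,
$s^2$ is always the pooled within-group (residual) variance, so real
effects do not masquerade as overdispersion.

Two validation operations close the loop: `label_permutation_null()`
re-runs the whole test-and-call pipeline under group-size-preserving label
permutations (identity and mirror excluded; empirical p with the +1
correction), and `subset_reanalysis()` drops nominated samples (e.g.
karyotypically abnormal lines) and reports DOCS overlap and log2FC
concordance.

## Region-set enrichment

`permutation_enrichment()` compares the number of query regions
overlapping an annotation (≥ 1 bp, half-open) with a null obtained by
redrawing each query interval uniformly on its own chromosome with its
own width. The summary is
$\mathrm{log2FE} = \log_2\frac{\mathrm{obs} + c}{\overline{\mathrm{null}} + c}$
with pseudocount $c = 1$ keeping it finite for rare annotations, and a
one-sided empirical p $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$;
depletion is read from log2FE $< 0$. BH adjustment is applied across the
whole batch of (query × annotation × cell type) tests before any
averaging. `aggregate_group_enrichment()` then averages log2FE and FDR
over the cell types of a group (pluripotent, germ-layer, other) and flags
an annotation when mean FDR $< 0.05$ *and* mean log2FE $> 0$;
`log2fe_ratio()` contrasts two query sets (Bi-DOCS vs Fi-DOCS) as the
difference of cell-type-mean log2FE — the log2 of the fold-enrichment
ratio, antisymmetric under swapping the queries.

Choices worth stating: the null preserves chromosome and width but not
inter-peak spacing (the simplest defensible random-regions null); there
is no GC or mappability matching; `n_perm` defaults to 1,000. The
empirical p is discrete, so with small queries its distribution is
super-uniform (conservative) because of ties between overlap counts —
calibration checks in the test suite use queries large enough that the
count distribution is smooth.

## Regulatory domains, pathways, and overlap tests

Region-to-gene association follows the basal-plus-extension convention:
each gene's basal window (5 kb upstream / 1 kb downstream of the TSS,
strand-oriented) is extended outward to the nearest neighbouring basal
domain, capped at 1 Mb and clipped to the chromosome; a region belongs to
every gene whose domain contains its midpoint. The midpoint rule makes
the null of the region test exact: with $n$ regions and a term's merged
domain union covering genome fraction $\pi$, the hit count is
Binomial$(n, \pi)$, tested on the upper tail, with region fold enrichment
$k/(n\pi)$. Genes are tested by the upper-tail hypergeometric on an
explicit universe (never defaulted silently), with gene fold enrichment
$(k_g N)/(K n_g)$. Terms are flagged by the compound rule: both BH-FDRs
(adjusted separately per test family across terms) below 0.05 and both
folds above 2. `fisher_overlap_test()` gives the two-sided Fisher exact p
by the point-probability convention with the sample odds ratio
$(ad)/(bc)$; a zero margin yields p = 1 and an undefined OR. These tails
are computed by the standard library routines and are verified against
direct log-space summation and full-enumeration oracles to $10^{-12}$ in
the test suite.

## Expression integration

`stage_differential_expression()` reuses the NB machinery on gene counts
per developmental stage (definitive endoderm, pancreatic progenitor);
DE calling uses the FDR threshold only — no fold-change floor — with a
floor available by argument for symmetry with DOCS calling.
`docs_expression_enrichment()` tests, per stage, whether genes up in
group A are enriched among Bi-DOCS-associated genes and genes up in
group B among Fi-DOCS-associated genes (hypergeometric upper tail on the
tested-gene universe, BH across the stage × direction grid), using the
same domain/midpoint association as the pathway stage for internal
consistency.

## The synthetic study generator

Real deposited sequencing data are not bundled, so `simulate_study()` is
the canonical input source and every statistical claim in the test suite
is checked against its planted truth. It emulates, at desk scale, a
two-group iPSC ATAC study: a 2 × 10 Mb genome; 10,000 non-overlapping
peaks of 200–800 bp; 5 vs 5 samples with lognormal size factors
(sd 0.2); per-peak base means lognormal around a median depth of 50;
NB dispersion Gamma-distributed with mean 0.15, a conventional scale for
chromatin count data (individual checks that posit a specific constant
$\alpha$ pass it explicitly); 10% differential peaks at
$|\mathrm{log2FC}| = 1.5$ with
58% more open in group A, matching the direction imbalance such studies
report; 4 cell types × 5 chromatin states tiling 5–10% of the genome in
~20 kb segments; 2,000 genes and 50 terms of 20–40 genes; and stage-wise
RNA counts (4 vs 4, depth ~100) whose differential expression is coupled
to the planted peaks with probability 0.8 plus a 2% background rate.

Two planted structures matter for interpretation. Differential peaks are
placed inside a designated state with probability
$\min(1, \rho \cdot \mathrm{coverage})$ and in its complement otherwise,
so their in-state rate is $\rho \cdot \mathrm{coverage}$ and the expected
log2FE against that state is $\log_2 \rho$ (the default $\rho = 4$ gives
2.0); non-differential peaks are uniform. One designated term's genes
have their TSS planted 1–4 kb from differential peaks on the
basal-upstream side, so the compound term-calling rule should flag
exactly that term. Seeding is hierarchical — each stage derives a child
stream from the master seed and its stage name — so outputs are byte-
reproducible and adding a stage never perturbs earlier ones.

What the generator does *not* emulate: read-level artefacts (GC and
mappability bias, duplicates), donor genetic structure, peak-width/signal
correlation, and correlated dispersion structure. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under the
stated generative model, not that any particular biological dataset will
meet the same error rates.

## Numerical and engineering choices

- Coordinates are 0-based half-open everywhere; 1-based dialects must be
  converted at the reader boundary. Chromosome names are compared as
  exact strings; `check_chrom_names()` surfaces mismatches instead of
  silently renaming.
- Overlap means ≥ 1 shared bp; there is no minimum-fraction option.
- Newton iterations stop at a $10^{-8}$ step norm with damping of steps
  larger than 5 log units; non-converged features are flagged and
  excluded from BH with a warning.
- `alpha_min` is $10^{-4}$; variance at or below the mean floors there.
- Size factors fall back to column-sum ratios when fewer than 100
  features are positive in every sample.
- Hierarchical clustering orders samples lexicographically before
  `hclust` so ties break deterministically; the distance is
  1 − Spearman rho with average linkage.
- PCA uses the top 5,000 features by variance, centring only — whether a
  variance filter is used at all is a documented knob, since conventions
  differ.
- The pipeline records an MD5 manifest of every output; deterministic
  stages reproduce identical hashes on rerun.

## Problem sizes used in the checks

The shipped tests run the full chain at the generator's default scale
(10,000 peaks, 5 vs 5; 500 calibration repetitions at 200 permutations;
50 label permutations; 10 generator seeds for the term-calling check),
the scale at which the statistical properties above were measured.

## Known limitations

Only two-group designs are supported — no covariates, donor random
effects, or shrunken fold-change estimators. The trended dispersion
deliberately ignores feature-specific dispersion beyond the mean trend;
with strongly heterogeneous true dispersions the `"eb"` method is the
safer choice and the normal Wald reference will be mildly
anticonservative in the extreme tail of high-dispersion features. The
enrichment null does not control for GC, mappability, or peak clustering.
Term calling assumes flat term sets (no ontology DAG propagation).
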