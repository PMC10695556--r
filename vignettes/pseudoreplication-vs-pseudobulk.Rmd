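---
title: "Pseudoreplication versus pseudobulk differential expression in snRNA-seq"
author: "pseudobulkDE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoreplication versus pseudobulk differential expression in snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudobulkDE)
```

## The problem

In case/control single-nucleus RNA-seq, the donor — not the nucleus — is the
unit of biological replication. Cells from one donor share that donor's
genetics, pathology, dissection and library preparation, so their expression
values are correlated. A differential-expression (DE) test that treats every
cell as an independent replicate ("pseudoreplication") computes standard
errors as if it had thousands of independent observations when it actually
has a few dozen, and its false-discovery control collapses: the number of
"significant" genes grows with the number of cells profiled rather than with
any biological signal. Pseudobulk analysis restores valid inference by
summing counts over all cells of one donor (per cell type) and testing at
the donor level.

This package implements both procedures, a hierarchical count simulator
with known ground truth, the nucleus-level QC cascade used in practice, and
a donor-label permutation benchmark that measures the inflation directly.
It also ships, as plain-text fixtures, the donor-level DEG tables of a
published pseudobulk reanalysis of the first Alzheimer's-disease snRNA-seq
cohort, whose headline numbers (26 unique DEGs versus 14,274 cell-level
DEGs — a 549-fold difference at the same FDR threshold) anchor the worked
examples.

## The simulation model

`generate_dataset()` draws counts for gene $g$, cell $c$ of type $t$ from
donor $d$ as

$$ y_{gc} \sim \mathrm{NB}\!\left(\mu_{gc},\ \phi_g\right), \qquad
   \mu_{gc} = s_c \exp\!\big(\log \mu_{gt} + u_{gd} + \beta_{gt}\,
   \mathbb{1}[d \text{ is case}]\big), $$

with per-gene, per-cell-type log-normal baselines $\mu_{gt}$, log-normal
cell size factors $s_c$, NB dispersion $\phi_g$
($\mathrm{Var} = \mu + \phi\mu^2$), and gene-by-donor random effects
$u_{gd} \sim N(0, \sigma_d^2)$. The random effect is gene-specific rather
than a single donor-level scalar, so it cannot be absorbed by per-cell
normalisation — exactly the kind of dependence that survives real
preprocessing. Truly DE genes (a configurable fraction per cell type,
independent across cell types) carry $\beta_{gt} = \pm\log(2)\cdot
\mathrm{de\_lfc}$ with Rademacher sign; the ground truth is returned
alongside the counts.

Two QC artifacts are layered on top. *Dying cells* (default 10% of cells)
have their counts redistributed so that the mitochondrial proportion
follows a Beta(8, 2) law (mean 0.8) while the cell's total is preserved;
mitochondrial genes are named with the conventional `MT-` prefix. *Doublets*
(default 5% of emitted barcodes) are element-wise sums of two cells drawn
uniformly within one donor — droplet doublets are within-sample events —
and are flagged in the metadata rather than detected, since doublet
detection algorithms are out of scope.

Default cohort: 24 case and 24 control donors, six cell types whose
expected per-donor cell numbers span a 10:1 range (excitatory neurons 150
down to microglia 15), 2,000 genes at snRNA-seq-like depth (roughly 600
counts per cell). One integer seed drives every draw; identical seeds give
bit-identical datasets.

### Choosing the donor effect size

The literature this package engages with does not report intra-donor
correlation magnitudes, so $\sigma_d$ had to be calibrated. We swept
$\sigma_d \in [0.08, 0.4]$ under the permutation benchmark (12+12 donors,
2,000 genes, no true DE) across several generator seeds before freezing
anything else. Below $\sigma_d \approx 0.1$ the cell-level inflation
disappears at this depth; at $0.25$ and above the cell-level test fabricates
hundreds of DEGs per permutation, but the donor-level noise is then so
dominant that even a well-behaved donor-level likelihood-ratio test shows
occasional far-tail miscalibration at 24 donors. The default
$\sigma_d = 0.18$ sits in between: the cell-level test finds several dozen
false DEGs per label permutation (and their number tracks cell counts with
$r > 0.9$), while pseudobulk typically finds none.

## Quality control

`qc_filter()` reproduces the standard nucleus-level cascade:

| criterion | default | notes |
|---|---|---|
| minimum library size | 200 counts | fixed floor |
| minimum expressed genes | 200 genes | a gene is "expressed" with ≥ 2 counts in ≥ 3 cells, computed once on the full pre-QC matrix |
| maximum library size / expressed genes | median + 4·MAD | adaptive upper tail only; MAD without the 1.4826 consistency constant |
| mitochondrial fraction | ≥ 0.10 fails | inclusive cut-off by default (configurable to strict >) |
| doublets | dropped | consumes the metadata flag |

Criteria are evaluated independently, so one cell can fail several checks;
per-criterion failure counts overlap, and only total-failed plus
total-passed sums to the number of input cells. The accounting table that
`apply_qc()` returns makes that explicit. A constant vector has MAD 0; the
adaptive threshold then returns $+\infty$ (no upper outliers) with a
warning. Cells with zero totals get mitochondrial fraction 0 and a
degenerate-library flag. The expressed-gene mask is computed in a single
pass on the pre-QC matrix (no iterative re-masking after cell removal);
both choices are flagged in the documentation because published pipelines
rarely state them.

## Donor-level DE: pseudobulk NB-GLM with likelihood-ratio tests

`pseudobulk_de()` sums counts to one sample per (donor, cell type) —
samples with fewer than 10 cells are dropped (configurable; published
pipelines are silent on this) — filters genes (CPM > 1 in at least the
smaller group's number of samples), computes TMM normalisation factors
(30% two-sided log-ratio trim, 5% abundance trim, inverse-variance
weights, geometric mean 1), and fits, per gene,

$$ \log \mu_{gj} = \beta_{0g} + \beta_{1g}\,x_j + \log(N_j f_j), $$

an NB GLM with offsets equal to log effective library size. The condition
term is tested by a likelihood-ratio test: $LR = D_0 - D_1 \sim \chi^2_1$,
fold changes are $\beta_{1g}/\log 2$, and p-values are BH-adjusted within
each cell type (global adjustment is available; the reference tables this
package mirrors were adjusted per cell type, as their adjusted p-values'
magnitudes show). The GLM core is implemented in the package itself —
vectorised IRLS across genes with closed-form 2×2 weighted least squares —
rather than delegated, because the test's behaviour *is* the object of
study; the established implementation is used as an independent
cross-check in the test suite, where TMM factors agree to 1e-10 and the
Poisson-limit LR matches a `glm()` deviance oracle to better than 1e-4.

### Dispersion estimation

Per gene we evaluate the Cox–Reid adjusted profile likelihood (APL) of the
dispersion on a 19-point log grid spanning $[10^{-4}, 20]$, then shrink by
weighted-likelihood empirical Bayes: the maximised objective is the
gene-wise APL curve plus `prior_df` (default 10 effective samples, relative
to the gene's residual degrees of freedom) times the trend curve, where the
trend is the abundance-local mean of the (per-gene maximum-centred) APL
curves, computed as a moving average over abundance-ordered genes.
Curve-level shrinkage matters: shrinking *point estimates* lets a gene
whose likelihood is flat sit at the grid boundary ($\phi \to 10^{-4}$) and
subsequently test as near-Poisson, which manufactures false positives.

One further guard is on by default (`disp_floor_trend = TRUE`): the
dispersion used for testing may exceed the trend but not fall below it.
With a few dozen samples, below-trend gene-wise estimates are dominated by
estimation noise, and they are biased low in exactly the dangerous
configuration — when a condition split happens to align with a gene's
donor-level variability, the split absorbs that variability into the group
means, deflating the dispersion estimate and inflating the LR for the same
gene at the same time. Flooring at the trend removes this circularity. In
our calibration runs it reduced the permutation-null median DEG count from
about 1 to 0 without measurable cost: with independent cells
($\sigma_d = 0$) the raw false-positive rate stays at ~0.05, simulated
log2 fold changes of 2 are recovered with mean error < 0.05, and power at
FDR 0.05 on strongly DE genes remains ~0.95. Genes whose IRLS does not
converge (e.g. complete separation driven to the ±20 coefficient clamp) are
flagged; all-zero genes are excluded with a warning.

## Cell-level DE: the pseudoreplication procedure under study

`wilcoxon_de()` implements the cell-level analysis it critiques: within a
cell type, each cell is normalised to counts per ten thousand and
log1p-transformed (the original transformation behind published cell-level
analyses is typically unstated; raw counts are available via `normalize =
"raw"`), and each gene is tested between case and control *cells* with a
two-sample rank-sum test — mid-ranks, tie-corrected variance, continuity
correction, and exact enumeration of all group assignments when both groups
have at most 8 cells (the enumeration is exact under ties and costs at most
$\binom{16}{8}$ assignments). Fold changes are log2 ratios of group means
of the normalised expression with a $10^{-9}$ pseudo-count, since a
cell-level fold-change convention is likewise not standardised. BH
adjustment is per cell type. The per-gene mid-ranks and tie corrections do
not depend on the labels, so the permutation benchmark computes them once
and reuses them across label shuffles; results are identical to calling
`wilcoxon_de()` per permutation.

## The permutation benchmark

`run_benchmark()` permutes the case/control labels *at the donor level*
(never per cell — within-donor dependence is the phenomenon under test,
and cells inherit their donor's new label), reruns both DE procedures, and
records DEG counts per cell type at FDR 0.05. Permutation 0 is always the
observed labelling, so the benchmark subsumes the primary analysis;
permutation $i$ uses seed `base_seed + i`, making runs resumable and
reproducible. Group sizes are preserved by construction. A method that
fails on a permutation (for example, a rare cell type losing one condition
entirely after sample dropping) is recorded as missing for that
permutation, not fatal. Permutations are unconstrained — no covariate
balancing — since the design carries no covariates.

Under permuted labels there is no condition effect, so every DEG is a false
discovery. The two diagnostic readouts are the per-method median DEG count
across permutations and the Pearson correlation between per-cell-type mean
DEG counts and post-QC cell counts (`deg_cellcount_correlation()`). On
default synthetic data the cell-level procedure shows a near-perfect
positive correlation ($r > 0.9$) and tens of false DEGs per permutation,
concentrated in the most abundant cell types; pseudobulk shows a median of
zero with no positive correlation. With $\sigma_d = 0$ both procedures are
calibrated — the inflation is entirely a property of ignoring within-donor
dependence, not of the rank-sum test itself.

## Problem sizes and numerical choices

The shipped analyses use scaled-down cohorts chosen to keep the full suite
comfortably reproducible on a laptop: the benchmark runs 12+12 donors,
2,000 genes, six cell types (about 5,500 cells post-QC) and 10
permutations; calibration and recovery checks use 8+8 donors. These sizes
were fixed alongside the other defaults, and all headline behaviour
(inflation, correlation, calibration) is already unambiguous at this scale.

Numerical details that affect reproducibility: IRLS iterates to a $10^{-10}$
coefficient tolerance with linear predictors clamped to $[-30, 30]$ and
condition coefficients to $[-20, 20]$; NB deviances switch to their Poisson
limit below $\phi = 10^{-8}$; the dispersion grid maximum is refined by
quadratic interpolation; log-CPM abundance uses a 0.5-count offset. The
`logCPM` column reported alongside results is
$\mathrm{mean}_j \log_2\!\big((y + 0.5)/(N_j f_j + 1)\cdot 10^6\big)$,
an approximation to the reference tables' column semantics.

## What the simulation does and does not show

The generator reproduces the *statistical structure* the pseudoreplication
argument rests on: within-donor correlation, very unequal cell-type
abundances, NB overdispersion, library-size variation, dying cells and
doublets. It deliberately omits ambient RNA at the raw-droplet level,
gene–gene correlation networks, batch effects and cell-type
misclassification. Passing benchmarks on this data therefore demonstrate
the inflation mechanism and the pseudobulk remedy; they do not certify any
pipeline against every artifact of real tissue. The printed reference
tables serve the complementary role: they tie the package's summaries to a
real cohort's published numbers (26 versus 14,274 DEGs; median |log2 FC|
2.34 versus 0.16), which the worked examples reproduce exactly from the
shipped fixtures.

## Known limitations

* The NB-LRT references $\chi^2_1$ without small-sample correction; with
  very few donors its far tail is optimistic. The dispersion trend floor
  mitigates but cannot remove this — quasi-likelihood F-tests would, and
  are deliberately out of scope.
* Only a two-group design without covariates is supported.
* The two-stage cell-level + donor-level rule used by some published
  combinatorial analyses is provided only as a table intersection utility
  (`two_stage_deg_filter()`); donor-level mixed models are not
  reimplemented.
* `deg_summary()` percentages are integer-rounded shares of DEG *rows*
  (a gene significant in two cell types counts twice in the denominator),
  matching the convention of the reference tables.
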