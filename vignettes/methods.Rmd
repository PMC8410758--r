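---
title: "Models and methods behind orgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orgrowth implements the quantitative core of a brain-organoid overgrowth
study design: patient- and control-derived forebrain organoids, several
iPSC lines per genotype and several organoids per line, measured over weeks
in culture, with a CRISPR-corrected rescue line, bulk transcriptomes, and
cell-cycle labeling. This vignette explains each model, the choices we made
where the underlying procedures are usually left unstated, and what the
synthetic-data generators do and do not emulate.

## Morphometry

Organoid size is measured from binary segmentation masks, which are inputs
— the package performs no segmentation. `mask_area()` is foreground pixel
count times pixel area; `stack_volume()` the voxel analogue. The "middle
section" of a z-stack is the plane with 0-based index `floor(n_z / 2)`, an
arbitrary but fixed convention so even-depth stacks are handled
deterministically. `fit_linear()` is ordinary least squares of volume on
middle-section area, reported with $R^2$, $F(1, n-2)$ and its p-value; for
simple regression these satisfy the identity $R^2 = F/(F + \mathrm{df}_2)$,
which the test suite asserts on every fit. Projected area uses the raw
mask, not its convex hull; for lobed organoids the two differ, and raw
masks are the conservative choice.

Areas are reported in mm² and volumes in mm³; pixel and voxel sizes travel
with the mask objects and are supplied by the caller when reading TIFF
files — they are never guessed from image metadata.

## Growth model and the genotype test

Comparisons of case versus control organoids use a Gaussian random-intercept
model on the log scale,

$$\log y_{ij} = \beta_0 + \beta_1\,\mathrm{genotype}_i + b_{\mathrm{line}(i)}
  + \varepsilon_{ij},\qquad
  b \sim N(0, \sigma^2_{\mathrm{line}}),\;
  \varepsilon \sim N(0, \sigma^2),$$

so line-to-line variability is a multiplicative random effect and $\beta_1$
is a log fold change. The log scale matches how size effects are reported
(fold changes) and keeps positive-valued responses positive. The labeling
index, already a fraction, is modeled on its raw scale.

`fit_lmm()` maximizes the *full* likelihood, not REML, because genotype
significance comes from likelihood-ratio tests between models that differ
in their fixed effects, and REML likelihoods are not comparable across
fixed-effect structures. The likelihood is profiled over the variance ratio
$\lambda = \sigma^2_{\mathrm{line}}/\sigma^2$: given $\lambda$ the fixed
effects are generalized least squares and $\hat\sigma^2$ is closed-form, so
the outer problem is one-dimensional. We evaluate a log-spaced grid
($10^{-6}$ to $10^{3}$, 60 points, plus the boundary $\lambda = 0$) and
refine with `optimize()` (golden-section) to $10^{-10}$; there is no random
initialization, so fits are bit-reproducible. The boundary estimate
$\hat\sigma_{\mathrm{line}} = 0$ is allowed, where the fit provably
collapses to OLS. The test suite cross-checks coefficients, likelihood and
variance components against lme4's ML fits.

`lrt_genotype()` compares the genotype model to the intercept-only model:
$\chi^2 = 2(\ell_{\mathrm{full}} - \ell_{\mathrm{null}})$ with 1 df for a
two-genotype design. Negative statistics beyond round-off ($< -10^{-8}$)
are treated as optimizer failure; smaller ones are clamped to zero. A
permuted-label null simulation (1000 label permutations of a
3-lines-per-genotype, 7-organoids-per-line design) keeps the empirical
type-I error in [0.03, 0.07] at $\alpha = 0.05$ and runs as a standing
acceptance test. With 6 lines the asymptotic $\chi^2(1)$ reference is an
approximation; the calibration test is what justifies it at this design
size.

## Cell-cycle estimation

The labeling index is the fraction of cycling (Ki67+) cells that
incorporated BrdU during a short pulse. Within an organoid, section counts
are *pooled* (summed) before dividing — sections have unequal denominators,
so averaging per-section ratios would weight small sections too heavily —
and organoid-level indices are then averaged within a line. For a fixed
S-phase length the cycle length is $T_c = T_s / \mathrm{LI}$. $T_s$ is a
configuration parameter defaulting to 4.5 h, a typical human
neural-progenitor S-phase length; absolute $T_c$ values are always reported
together with the $T_s$ used. Genotype comparisons use
`relative_cell_cycle()`, in which $T_s$ cancels exactly:
$T_c^{\mathrm{patient}} = T_c^{\mathrm{control}} / \text{LI-fold}$.

Absolute cell numbers follow hemocytometer arithmetic
(`total_cells()`: chamber count / chamber volume × dilution × suspension
volume) and marker-positive counts are rounded totals × fractions
(ties-to-even).

## Permutation-null enrichment

The enrichment question is always the same: is the overlap $x$ between a
query set (differentially expressed genes) and a target set (a disease
annotation list, a co-expression module, the top loadings of a principal
component) larger than random sets would give? The null is built directly:
`n_perm` draws of a query-sized set, uniform without replacement from a
gene universe, each intersected with the target; then
$z = (x - \mu)/\sigma$ against the null sample mean and SD (ddof 1), with
the two-sided normal p-value as the primary summary and the empirical
permutation p-value $((\#|x_{\mathrm{null}}-\mu| \ge |x-\mu|)+1)/(n_{\mathrm{perm}}+1)$
reported alongside.

This null is exactly hypergeometric, so `hypergeometric_moments()` provides
the closed form
$\mu = qK/N$, $\sigma^2 = \mu(1-K/N)(N-q)/(N-1)$ as an independent oracle;
the tests verify the permutation moments against it, against exhaustive
subset enumeration on tiny universes, and verify that the null $z$ is
centred at zero over hundreds of random queries. For a query of 339, a
target of 980 and a universe of 20000 the oracle gives $\mu = 16.61$,
$\sigma = 3.94$.

The universe is a genuine modelling choice the procedure is sensitive to:
we default to *all genes in the supplied DE table* (every gene actually
tested), overridable by an explicit list. Identifier matching is
case-folded and whitespace-stripped; no alias databases are consulted.
Significance thresholds use strict inequality, `padj < alpha`, with
Benjamini–Hochberg adjustment computed internally (via `p.adjust`) when
only raw p-values are present.

Two variants reuse the same machinery. `direction_reversal()` finds genes
significant in two contrasts (disease vs control; rescue vs disease) with
opposite effect signs — evidence of phenotype rescue. Its null draws a
random set the size of the second significant set and flips a fair coin for
the sign of each co-significant gene; the coin-flip null is our choice, as
reversal nulls are rarely specified precisely. `top_loading_genes()` takes
the k genes with largest *absolute* loading on a principal component
(ties broken lexicographically) so that batch-driven components can be
tested for (non-)overlap with DE sets.

## Identity mapping

`correlate_profiles()` ranks labelled reference profiles (structure × age)
by Pearson correlation with a query profile over a high-expression gene
panel — `top_expressed_genes()` picks the top-n genes by mean expression
across query samples (mean rather than median or max; ties
lexicographic). Counts are correlated on the log2(x+1) scale; values that
are already summarized can be correlated raw via `is_counts = FALSE`. The
mean profile across query samples is the default; correlating per sample
and averaging r is available by calling the function per column. Matching
is silent when ≥ 90% of the panel is found, warns below that, and errors
below 10 shared genes. Constant profiles get an undefined r and rank last.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

* `gen_morphometry()` — 3 lines per genotype × 7 organoids per line over
  weeks 4–13, log-scale growth with a line random intercept (SD 0.10), a
  residual SD of 0.15, a genotype fold effect ramping to 1.5× at week 13,
  and a linear area→volume relation. A baseline growth rate of 0.2
  log-units/week (about 1 mm² at week 4 growing ~6-fold by week 13) is our
  addition: longitudinal growth needs a trend, and brightfield time courses
  of cortical organoids are of this magnitude. Between-organoid SDs are
  free parameters, not calibrated to any dataset.
* `gen_brdu_ki67()` — per-section double-positive counts
  Binomial(n_Ki67, LI), 3 organoids per line and 3 sections per organoid,
  with genotype labeling indices defaulting to $4.5/83$ and $4.5/54$ so
  that cycle-length estimation recovers an ~83 h vs ~54 h contrast.
* `gen_expression()` — log-normal baseline means, negative-binomial counts
  (dispersion 0.1), 339 planted DE genes among 20000, a 980-gene disease
  set overlapping the DE set by exactly 19, a rescue condition that
  reverses each DE gene's sign independently with probability 67/339, and
  a batch effect: rescue samples form a second batch whose shift loads on
  a 5% gene subset disjoint from the DE genes, so PC1 captures batch and
  overlaps the DE set only at chance level. Truth tables carry synthetic
  p-values (planted genes uniform on $[0, 10^{-8}]$, nulls uniform on
  $[0,1]$, BH-adjusted), which makes the threshold machinery behave as on
  a real DE run — including a realistic handful of false positives.
* `gen_atlas()` — labelled reference profiles plus a query equal to one
  profile with log-scale noise (SD 0.1), so correct top-ranking is
  guaranteed under small noise and degrades to chance as noise dominates.

None of this simulates read-level RNA-seq, single-cell structure, image
texture, or segmentation error; passing tests demonstrate that the
*procedures* are correct and calibrated, not that any biological claim
holds on real data.

## Numerical conventions and edge cases

* Ratios with zero denominators (Ki67 = 0 units, empty universes, GM+WM=0)
  are errors or dropped-with-warning, never silent NaN.
* Empty masks and stacks return 0 with a warning.
* A constant response in the LRT yields $\chi^2 = 0$, $p = 1$ rather than
  a degenerate likelihood.
* Both constant samples with equal means give Welch $p = 1$; with unequal
  means the statistic is undefined and raises an error.
* The "weighted z-score" combination is Stouffer's
  $\sum w_i z_i / \sqrt{\sum w_i^2}$; we expose both tails because
  published summaries are often ambiguous about which was used. Weights of
  $\sqrt{n}$ per stratum are the intended use.
* p-values are reported at full precision; `report_style = "paper_rounded"`
  formats them to 1–2 significant figures for comparison with printed
  values.

## Problem sizes

The standing test and acceptance runs use the study-scale designs where
they are cheap (20000-gene universes, 10000 permutations, 1000
permuted-label LMM fits, 100-seed recovery loops) and scaled-down universes
(2000 genes) for unit tests of the same code paths; each choice is stated
where it is made.

## Known limitations

* The asymptotic $\chi^2(1)$ LRT reference at 6 lines is justified
  empirically (calibration test), not theoretically.
* One published pairing of a $\chi^2(1)$ statistic and p-value
  (13.25 with p = 0.00043) is not internally consistent (the tail of 13.25
  is 2.7×10⁻⁴); the package computes tails from statistics and takes no
  side on such discrepancies.
* Enrichment z-scores depend on the universe definition, which published
  analyses frequently leave unstated; identical overlaps can yield
  different z under different universes, and the package therefore always
  records universe size in its results.
* `simulate()` on a fitted LMM re-draws line intercepts; it does not
  condition on the estimated ones.
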