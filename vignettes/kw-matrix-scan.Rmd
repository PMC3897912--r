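---
title: "Matrix-based Kruskal-Wallis eQTL scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-based Kruskal-Wallis eQTL scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kwscan)
```

## The statistical problem

An eQTL scan tests every genetic marker against every molecular trait:
with $M$ markers, $N$ traits and $K$ samples, $M \times N$ group
comparisons.  The Kruskal-Wallis test is attractive here because it
assumes nothing about the trait distribution within genotype groups and
responds to any shift in group medians, which makes it robust to
expression outliers and to non-additive genetic effects.  Its drawback is
computational: calling a per-pair test function billions of times is
prohibitive, and permutation-based multiple-testing correction multiplies
the cost further.

`kwscan` removes that bottleneck by computing every pair's statistic at
once with a handful of matrix products.

## The matrix formulation

Let $\mathbf{G}$ be the $M \times K$ genotype matrix with integer codes
$0,\dots,\ell$ ($\ell = 2$ for biallelic SNPs) and $\mathbf{D}$ the
$N \times K$ expression matrix.  Each trait row of $\mathbf{D}$ is
converted to mid-ranks, giving $\mathbf{R}$.  For each genotype code $i$
the sparse indicator matrix $\mathbf{I}_i$ has
$\mathbf{I}_i(m,k) = 1$ iff $\mathbf{G}(m,k) = i$.  Then

$$\mathbf{S}_i = \mathbf{R}\,\mathbf{I}_i^{\mathsf T}$$

holds every group rank sum (trait $n$, marker $m$, group $i$)
simultaneously, and $N_i(m) = \sum_k \mathbf{I}_i(m,k)$ the group sizes.
The Kruskal-Wallis statistic of every pair is the element-wise expression

$$H(n,m) = \frac{12}{n(n+1)} \sum_{i=0}^{\ell}
  \frac{\mathbf{S}_i(n,m)^2}{N_i(m)} - 3(n+1),$$

with $n$ the number of jointly observed samples of the pair.  Three
corrections make this exact on real data:

* **Empty groups.** A marker that uses fewer than $\ell + 1$ codes
  produces $0/0$ terms; these are replaced by 0, which yields exactly the
  statistic of the test on the reduced set of groups.  The pair's degrees
  of freedom are (non-empty groups $-$ 1), re-counted per pair.
* **Ties.** With tied observations $H$ is divided by
  $1 - \sum T / (n^3 - n)$, $T = t^3 - t$ per tie group of size $t$.  The
  tie sums are accumulated once per trait during ranking.  The correction
  is applied unconditionally (it is the standard definition; without it
  the statistic is not chi-squared calibrated under ties).
* **Missing values.**  Missing expression values rank 0, so the rank sums
  need no adjustment; a 0/1 presence matrix $\mathbf{Z}$ multiplied
  against $\mathbf{I}_i^{\mathsf T}$ gives the per-pair group sizes, and
  $n$ becomes the trait's observed count.  Missing genotype calls are
  handled by grouping markers with an identical missing-sample pattern
  (sample-quality failures recur across markers), dropping exactly those
  samples, and re-ranking the traits on the retained samples -- so every
  pair's statistic equals the one-by-one test on its pairwise-complete
  samples.  Heavy, unstructured genotype missingness degrades this to
  many small partitions and is the one regime in which the matrix
  formulation loses its advantage.

Pairs with fewer than 2 non-empty groups, fewer than 3 jointly observed
samples, or a trait constant on the retained samples are *untestable*:
the chi-squared reference is meaningless there, and they are flagged and
excluded rather than reported as 0/0.

Markers are processed in contiguous **slices** (default 2,000 markers) so
the $N \times m$ intermediates stay small; results are independent of the
slice size, and a `start_marker` argument lets a scheduler farm out one
slice per job.  Accumulations are in double precision; rank sums are
integers well below $2^{53}$, so no compensated summation is needed.

## Significance and empirical FDR

Significance is asymptotic: $H \sim \chi^2_{df}$.  Rather than computing
$MN$ tail probabilities, the p-value cutoff $P_c$ is inverted once per
degrees-of-freedom value into a statistic threshold, and only pairs above
their threshold receive p-values.  The scan is more conservative in
nominal p-values than parametric alternatives, so nominal values are not
compared across methods; instead an **empirical FDR** is attached by
re-running the identical pipeline on data in which the sample columns of
the expression matrix are randomly permuted -- one permutation per round,
shared by all traits, so trait-trait correlation is preserved.  For an
association at p-value $p$,

$$\mathrm{FDR}(p) = \frac{\text{mean}_r\,\#\{p'_r \le p\}}
                         {\#\{p_{\text{real}} \le p\}},$$

capped at 1.  Raw ratios need not be monotone in $p$; by default a
running maximum from the smallest p-value enforces monotonicity
(`monotone_fdr = FALSE` gives the raw ratios).  Tied p-values pool (both
counts use $\le$) and share one FDR value.  A master seed draws one
sub-seed per round, so results are reproducible and independent of
slicing.  Three permutation rounds are enough to separate planted signal
from null background in the validation setting below; more rounds refine
FDR estimates near the cutoff.

When marker and gene positions are supplied, associations are restricted
to *cis* pairs -- same chromosome, marker within 1 Mbp (inclusive) of the
gene start -- *before* FDR counting, in the real and the permuted scans
alike, so the FDR is computed over the same hypothesis family that is
reported.  The gene start is used as a TSS proxy because transcript-level
annotation carries no extra information for a window this wide.

## eQTL classification

Associations at biallelic markers are typed by the mechanism that drove
them:

* **skewed** -- smallest non-empty genotype group under 5 samples.  These
  are the associations where parametric tests chase outliers and where
  any asymptotic approximation is shaky.
* **non-linear** -- not skewed, and the heterozygous samples differ from
  the pooled homozygous samples (two-sided Wilcoxon rank-sum test,
  $p < 0.05$).  Dominant alleles and heterozygote-outside patterns land
  here; a purely additive dosage effect usually does not.
* **other** -- everything else (mostly additive signals and noise).

The heterozygote group is compared against the *pooled* homozygotes: one
two-group test, rather than requiring both het-vs-hom comparisons to be
individually significant.  Pooling is the weaker (more sensitive)
criterion and needs no extra multiplicity handling; with a dominant
allele the pooled homozygote median sits between the two homozygote
medians, and the comparison still flags the pattern.  The rank-sum test
is `stats::wilcox.test`, which enumerates exactly for small untied groups
and otherwise uses the tie-corrected normal approximation.  Markers with
codes above 2, and degenerate pairs with fewer than two groups, are
`unclassified`.

## The synthetic panel generator

Real genotype and expression panels are large and access-controlled, so
validation runs on synthetic panels that emulate the relevant structure:

* **Genotypes**: each marker's minor allele frequency is drawn uniformly
  from `maf_range` (default `c(0.05, 0.5)`, mirroring the usual $>5\%$
  MAF filter on SNP panels) and genotypes follow Hardy-Weinberg
  proportions $((1-q)^2,\,2q(1-q),\,q^2)$.  Optional three-allele markers
  collapse the six Hardy-Weinberg genotype classes into four ordered
  codes, exercising the variable-allele-count path.
* **Expression**: unit-variance Gaussian noise plus planted effects.
  Effect sizes are in noise-SD units; `additive` is a per-allele dosage
  shift ($\beta g$, the standard quantitative-genetics parametrization),
  `dominant` shifts all carriers equally, `het-outside` shifts only
  heterozygotes, placing them outside the homozygote range.
* **Missingness and ties** are injected independently per cell at the
  spec rates; ties come from rounding to one decimal, the way count-based
  or discretised measurements tie in practice.
* **Positions**: five synthetic chromosomes of 200 Mbp; planted pairs are
  placed within 0.5 Mbp of their marker (guaranteed cis at a 1 Mbp
  window), everything else uniformly at random.

What the generator does **not** emulate: linkage disequilibrium between
markers, population structure, and realistic expression covariance.
Passing tests on these panels therefore establish the *algebraic*
correctness of the scan (equality with one-by-one testing, calibration,
power against planted effects) -- they do not establish field performance
on a structured cohort, where covariate adjustment of the expression
matrix is the user's responsibility before scanning.

## Validation and problem sizes

The test suite checks, among others:

* exact equivalence (relative tolerance $10^{-9}$; observed agreement is
  at machine precision) between the matrix scan and an independent
  per-pair implementation on 20 panels of 200 markers x 50 traits x 60
  samples with mixed bi-/triallelic markers, 10% missing genotypes, 5%
  missing expression and injected ties;
* exact invariance under slicing, under monotone transforms of every
  trait, and under raising the dataset allele count without carriers;
* type-I error and null-FDR behaviour on an effect-free
  1000 x 100 x 100 panel;
* $\ge 90\%$ recovery at empirical FDR $\le 10\%$ (3 permutation rounds)
  of 50 planted cis effects of 1.5 SD at MAF $\ge$ 0.2 in 100 samples,
  and a higher non-linear classification rate for dominant/het-outside
  plants than for additive ones.

These sizes keep the full suite in a few minutes while leaving every code
path (partitioning, presence-matrix counts, tie correction, slicing)
exercised on every panel.

## Known limitations

* The chi-squared reference for the Kruskal-Wallis statistic is slightly
  conservative at moderate sample size: on the null panel above
  (K = 100, MAF $\ge$ 0.05) the measured fraction of $p < 0.05$ is about
  0.045, not 0.050, and low-MAF markers with near-empty groups are the
  main contributors.  The empirical FDR is the intended significance
  currency and is unaffected; nominal p-values should not be read as
  exact sizes.
* Genotype missingness that does not repeat across markers forces one
  partition per marker and loses the matrix speed-up; filter on call
  rate first.
* Covariate adjustment, normalisation and quality control of the
  expression matrix are out of scope and assumed done.
* VCF/PLINK import is out of scope; convert with
  `bcftools query -f '%ID[\t%GT]\n'` (recoding `0/0`,`0/1`,`1/1` to
  0,1,2) or PLINK's `--recode A` into the tab-separated dialect.
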