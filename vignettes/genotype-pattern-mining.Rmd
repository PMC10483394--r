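---
title: "Exhaustive mining of variant and genotype pairs in case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive mining of variant and genotype pairs in case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmkit)
```

## The problem

Digenic traits are driven by the joint effect of two DNA variants, each of
which may show little or no marginal association with disease. A
single-variant genome-wide association scan therefore misses them. gpmkit
takes the opposite, brute-force route: with `N` biallelic variants there are
`M = N(N-1)/2` variant pairs, and each pair contains up to nine genotype
pairs (patterns). Every admissible pair is numbered, cross-tabulated against
the case/control phenotype, and tested. The workload is split into
contiguous blocks of the pair-id range, so multi-worker runs are bit-for-bit
identical to single-worker runs.

Two complementary engines are provided.

## The variant-pair interaction statistic

For one variant pair, the 3x3 table of known genotypes (codes 0/1/2 = A1A1,
A1A2, A2A2) has 8 degrees of freedom: 2 + 2 main effects and 4 interaction.
To test whether *interaction structure* differs between cases and controls,
irrespective of main effects, `interaction_test()` computes likelihood-ratio
independence statistics

$$G^2 = 2 \sum_j n_j \log(n_j / e_j)$$

separately for the case table, the control table, and their cellwise sum,
and forms

$$C = G^2_{case} + G^2_{ctrl} - G^2_{case+ctrl},$$

referred to a chi-square distribution with 4 df. `scan_variant_pairs()`
evaluates `C` for all admissible pairs. A pair only counts as a test when
every expected count in all three computations reaches `min_expected`
(default 1, user-settable); the number of analyzable pairs `M_t` is the
Bonferroni multiplier, `p_B = min(1, p * M_t)`, applied in a second pass
once `M_t` is known exactly.

Numerical conventions:

* `0 log 0` is 0; cells in all-zero rows or columns are structural zeros and
  are excluded from the expected-count screen.
* `C <= 0` is possible in Simpson-type configurations where the stratified
  tables are closer to independence than their sum. The chi-square null
  gives such pairs no evidence of interaction difference, so `C` is reported
  as computed and `p` is clamped to 1.
* A pair in which one phenotype group has no fully typed individual is not
  analyzable and carries no p-value.

`pairsnps_report()` is the drill-down: for a single pair it tabulates all
nine patterns with their 2x2 tables, support, confidence, and
Haldane-corrected odds ratios `OR = (a+1/2)(d+1/2) / [(b+1/2)(c+1/2)]`
(finite for empty cells) together with the direction-free
`OR' = max(OR, 1/OR)`.

## The genotype-pair engine and missing data

`scan_genotype_pairs()` tests each pattern's 2x2 phenotype-by-presence
table with either the Pearson chi-square or a Fisher exact test: `F2`
one-sided toward cases, `F1` one-sided toward controls, `F3` two-sided by
the point-probability rule (tables whose point probability is at most the
observed one within a relative tolerance of 1e-7).

Missing genotypes are handled exactly, not by subtraction from raw group
sizes: each pair is first cross-tabulated 4x4 with "missing" as a fourth
genotype class, and the pattern tables are built from the 3x3 known-genotype
subtable, so `a + b` and `c + d` are the numbers of cases and controls with
known genotypes at *both* variants. An individual missing either genotype is
neither "pattern present" nor "pattern absent".

Patterns are filtered before testing: support `a + c` must reach
`min_support` (default 10, the setting used for small cohorts; support-0
patterns are never tested because confidence `a/(a+c)` is undefined), and
confidence must reach `min_confidence` (default 0, no restriction). The
Bonferroni multiplier `tested_count` counts exactly the patterns actually
tested, which for the chi-square run additionally excludes patterns failing
the expected-count screen — a chi-square run and a Fisher run on the same
data may therefore use different multipliers, by design.

## ROC evaluation of top patterns

`binned_roc()` treats pattern presence as a phenotype predictor: under `F2`
the pattern predicts "case" (`TPR = a/(a+b)`, `FPR = c/(c+d)`), under `F1`
it predicts "control" (roles swapped). The `top_k` patterns by the matching
Fisher p-value each contribute one (FPR, TPR) point; the FPR axis is split
into `n_classes` equal-width classes (default 20, with `top_k = 100`) and
each nonempty class is represented by its within-class mean FPR and mean
TPR. Anchors (0,0) and (1,1) are always appended, empty interior classes
are filled at their midpoints by linear interpolation (collinear, so they
never change the area), and AUC is the trapezoid area of the anchored
polyline.

Using the within-class mean FPR as the abscissa, rather than the class
midpoint, was a deliberate choice: a degenerate perfect classifier (a
pattern with FPR = 0 and TPR = 1) then yields the exact unit curve
(0,0)-(0,1)-(1,1) with AUC 1, whereas a midpoint abscissa would shift the
point to 1/(2 `n_classes`) and cap the AUC below 1. Interpolation remains
deterministic because the fill positions are the fixed class midpoints.

Whether the top patterns should be de-duplicated so no variant appears
twice is left to the user (`dedupe`, default off): de-duplication gives a
curve over more independent predictors, but discards the strongest signals
when one variant pair dominates.

## The synthetic-data generator

`simulate_genotypes()` produces the datasets every scan is tested on.
Background variants are independent across individuals and variants, with
genotypes in Hardy-Weinberg proportions `(1-q)^2, 2q(1-q), q^2` at a
per-variant MAF drawn uniformly from `maf_range` (default 0.05–0.5, the
common-variant range of genotyping arrays). Chromosome labels are assigned
round-robin over `n_chromosomes` (default 22, mirroring autosomal panels).
Missingness is MCAR at `missing_rate` (default 0.02, a typical array
failure rate) and independent of phenotype and genotype — the simplest
mechanism that still exercises the 4x4-to-3x3 machinery.

A planted digenic effect is specified as a 3x3 table of disease-odds
multipliers over the genotype pairs of two chosen variants. Phenotypes
follow a logistic-odds model whose intercept is solved numerically
(`uniroot`) so the expected case fraction equals the requested one, and
individuals are drawn by rejection until exactly `n_case` cases and
`n_ctrl` controls are collected, keeping group sizes deterministic.

`pure_interaction_table(strength, maf1, maf2)` builds a multiplier table
with *no marginal effect*: starting from a checkerboard of `strength`
versus 1 (the canonical pure-epistasis pattern), rows and columns are
alternately rescaled to unit HWE-weighted mean (a weighted Sinkhorn
iteration, converged to 1e-13). This preserves the table's cross-ratios —
the interaction content — while making every row and column average out
under the genotype frequencies, so single-variant tests at the planted
variants stay null.

What the generator does **not** emulate: linkage disequilibrium between
variants (all background variants are independent), population structure
and relatedness, genotyping error correlated with plate or batch, and
informative missingness. Passing tests on these data therefore demonstrate
the statistics and their accounting, not robustness to the correlation
structure of real cohorts; on real data, LD pruning before a scan is the
user's responsibility, as is the cross-chromosome restriction
(`cross_chrom_only`) that removes the worst within-chromosome dependence.

## Worked example

The packaged worked example enters the published 96-case / 50-control
cross-tabulation of one variant pair directly:

```{r}
case3x3 <- matrix(c(1, 0, 10, 5, 26, 28, 5, 16, 5), 3, 3, byrow = TRUE)
ctrl3x3 <- matrix(c(2, 11, 0, 4, 10, 4, 0, 4, 15), 3, 3, byrow = TRUE)
interaction_test(case3x3, ctrl3x3)
min(1, interaction_test(case3x3, ctrl3x3)$p * 294643816)
haldane_or(two_by_two(0, 96, 11, 39))
```

## Problem sizes and calibration checks

The test suite validates the simulator and scans at sizes a laptop handles
in seconds to a couple of minutes, chosen to keep the whole suite quick
while leaving the statistical checks well-powered: parameter recovery uses
50 replicates of 500 cases / 500 controls by 50 variants with a planted
strength-6 pure interaction at MAF 0.3 (the planted pair must rank first in
at least 90% of replicates); null calibration uses 12 unplanted replicates
of 500/500 by 25 variants (mean type-I error at nominal 0.05 within
plus/minus 0.02) and 200 single-pair replicates for uniformity of the null
p-value. Fisher p-values are verified against brute-force hypergeometric
enumeration for tables with totals up to 60, and the pair-id inversion
against full loop enumeration up to 200 variants.

## Known limitations

* The 4-df chi-square reference for `C` is asymptotic; the expected-count
  screen (default 1) is the only small-sample guard, as in standard G-test
  practice.
* Bonferroni over `M_t` (or `tested_count`) is conservative under the
  dependence among overlapping pairs; permutation-based correction is out
  of scope.
* Only autosomal-style uniform handling of chromosomes is provided; sex
  chromosomes get no special treatment.
* Quantitative phenotypes and covariates are not supported; phenotypes are
  strictly case/control.
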