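---
title: "Forensic STR population statistics with strpopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic STR population statistics with strpopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopkit)
```

`strpopkit` implements the statistical pipeline of a forensic STR population
study: the per-locus forensic efficiency panel, exact equilibrium testing,
and inter-population comparison, with a synthetic genotype generator for
validation. This vignette is the package's account of the underlying models,
the estimators and their assumptions, the numerical choices made, and what
the synthetic validation does and does not establish.

## STR alleles and data quality

An autosomal STR allele is a repeat count, possibly with a partial repeat:
`9.3` means nine full repeat units plus three bases. The package stores
alleles as exact integer pairs `(repeat_units, partial_bases)` with
`partial_bases` in 0–3, never as floating-point numbers — `9.3` must not
compare equal to the number 9.3, and hashing and ordering must be exact.
Ordering is lexicographic on the pair, so `9.3` sorts between `9` and `10`.

Real capillary-electrophoresis data contain two kinds of per-call anomaly:

* **off-ladder (`OL`)** peaks that fall outside the kit's allelic ladder and
  cannot be assigned a named allele, and
* **tri-allelic patterns**, three peaks at one locus in one individual
  (usually a duplication).

Both are retained and reported by `detect_anomalies()`, but excluded from
frequency estimation and equilibrium testing at the affected locus: an `OL`
carries no usable allele identity, and a three-allele call has no diploid
genotype. Published studies report these events separately rather than
folding them into the frequency tables, and excluding them is the only
treatment that keeps the frequency denominator interpretable as an allele
count. The exclusion is visible: `allele_frequencies()` reports how many
calls it dropped, and the effective `2N` varies by locus accordingly.

Missing data are encoded as an explicitly empty call (both alleles `NA`);
half-missing calls are rejected at construction because they are not a
valid diploid state. Loci with fewer than two usable calls are skipped with
a warning by the summary functions.

## The forensic parameter panel

For a locus with allele frequencies $p_i$ estimated from $2N$ alleles, and
observed heterozygosity $h$ (fraction of usable calls with two distinct
alleles, $H = 1 - h$):

* expected heterozygosity $He = 1 - \sum_i p_i^2$, with the unbiased
  small-sample correction $\frac{2N}{2N-1}$ applied in the per-locus
  summary;
* polymorphism information content (Botstein)
  $PIC = 1 - \sum_i p_i^2 - \left(\sum_i p_i^2\right)^2 + \sum_i p_i^4$,
  which never exceeds the uncorrected $He$;
* random match probability $PM = \sum_g P(g)^2$ over genotypes $g$, and
  power of discrimination $PD = 1 - PM$;
* power of exclusion $PE = h^2 (1 - 2 h H^2)$;
* typical paternity index $TPI = \frac{1}{2(1-h)}$;
* the NRC minimum-allele-frequency floor $5/(2N)$, reported alongside the
  frequencies and never substituted into them (no silent flooring);
* across loci, $CMP = \prod_l PM_l$ and $CPD = 1 - CMP$, assuming linkage
  equilibrium between loci — which is why the LD screen below belongs to
  the same pipeline.

**Two match probabilities.** $PM$ has two common operationalizations: the
sum of squared *observed* genotype proportions, and its expectation *under
HWE*, which collapses to $2(\sum p^2)^2 - \sum p^4$. On real data the two
differ in the third decimal, and published tables do not always say which
was used. The package computes and labels both (`PM`/`PD` observed,
`PM_expected`/`PD_expected`), defaults the combined statistics to the
observed variant, and leaves the choice to the reader of the report.

$PE$ and $TPI$ are computed from the unrounded observed heterozygosity, not
from the 4-decimal value a report prints; exported tables are formatted to
4 decimals (5 for frequencies) purely at the writing stage.

## Exact equilibrium testing

**HWE.** With more than a few alleles, the chi-square test is unusable
(most genotype classes are rare), so the package implements the exact test
conditional on allele counts. The probability of a genotype array
$\{n_g\}$ given allele counts $\{c_a\}$ is

$$P(\{n_g\} \mid \{c_a\}) = \frac{N!\,\prod_a c_a!\,2^{H}}{(2N)!\,\prod_g n_g!},$$

with $H$ the heterozygote count. The null distribution is sampled by
re-pairing the observed $2N$ alleles into $N$ genotypes uniformly at
random; the p-value is the add-one Monte-Carlo estimate
$p = (1 + \#\{\text{arrays at most as probable}\})/(B+1)$, bounded below by
$1/(B+1)$ so a permutation p-value is never zero. Only the
$H\log 2 - \sum_g \log n_g!$ part of the statistic varies under re-pairing;
everything else cancels, and comparisons use a $10^{-9}$ slack so
floating-point noise cannot flip a tie. The allele vector is put in a
canonical sort order before sampling, making the p-value exactly invariant
to the row order of the input, not just in distribution. A monomorphic
locus admits a single array; the test returns $p = 1$ with a `degenerate`
flag rather than failing. For tiny samples the test suite checks the
Monte-Carlo p against exhaustive enumeration of all pairings.

**LD.** For a pair of loci the package tests association between unphased
single-locus genotypes directly — no haplotype inference, which would
require an EM step and additional assumptions. The statistic is the
log-likelihood-ratio $G$ on the genotype-by-genotype contingency table
(individuals as units); the null is generated by permuting one locus's
genotype column, which preserves both marginals (so the expected counts are
computed once). Default $B$ is 10,000 for both tests.

**Multiple testing.** `bonferroni_threshold(alpha, m)` is $\alpha/m$, and
`multiple_test_summary()` flags results below it. `m` is an explicit
argument everywhere: some studies set `m` to the number of tests, others to
the sample size; the pipeline defaults to the sample size N to mirror the
reporting convention of the study whose tables ship with the package, and
documents that this is a convention, not a statistical necessity.

## Inter-population comparison

Comparisons start from *published frequency tables*, not genotypes — that
is what is available for other populations. `align_loci()` restricts all
tables to their shared locus panel and takes allele unions per locus with
zero fill (a 21-locus study is compared with a 15-locus study on the 15
shared loci).

**FST.** Two estimators:

* `nei_gst`: per locus $(H_T - H_S)/H_T$ with $H_S$ the mean
  within-population expected heterozygosity and $H_T$ from the mean
  frequencies, loci combined by $H_T$ weighting. It needs nothing but the
  frequencies, which is why it is the default for literature comparisons.
  Note the well-known property that with $r$ populations its expectation is
  roughly $F\,(1-1/r)$ under a divergence level $F$ — for a *pair* of
  populations it estimates about half the Balding–Nichols $F$. That is a
  property of the quantity GST measures, not an implementation error.
* `weir_cockerham`: the two-level variance-components estimator
  $\theta = \sum a / \sum (a+b+c)$, which does recover the divergence
  parameter. Published tables carry no genotypes, so the heterozygosity
  component is taken at its HWE expectation $2p(1-p)$ and per-population
  sample sizes must be present on the tables. Parameter-recovery tests
  (simulated divergence $F = 0.05$, 2 populations, 15 loci of 8 alleles,
  N = 500, 20 seeds) use this estimator and recover $F$ within $\pm 0.02$.

Sampling noise near zero divergence can make either estimator slightly
negative; pairwise values are clamped to 0 with a message, keeping distance
matrices valid input for tree building.

**Nei distances.** Standard $D_s = -\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$
with the gene-identity sums $J$ accumulated over loci and alleles, and
$D_A = 1 - \frac{1}{L}\sum_l \sum_i \sqrt{x_i y_i}$. A pair sharing no
alleles anywhere has infinite $D_s$; it is reported as the largest finite
distance plus one, flagged by a message, rather than propagating `Inf`
into the tree.

**Neighbor-joining.** Implemented in-package (Saitou–Nei agglomeration with
the standard Q-criterion) so that two behaviors are pinned: ties in Q are
broken by the lowest (row, column) index pair, making results fully
deterministic, and negative branch-length estimates — possible for
non-additive input — are clamped to zero with the negative amount
transferred to the sibling branch, preserving the joined pair's path
length. For additive matrices the generating tree is recovered exactly
(checked to 1e-9 against path-length recomputation, and cross-checked
against `ape::nj` topologies). Trees are `ape` `phylo` objects; Newick
serialization quotes labels containing spaces or Newick metacharacters.

**Nonmetric MDS.** Kruskal's stress-1 formulation: classical (Torgerson)
scaling provides the start, monotone disparities come from
pool-adjacent-violators, and the optimization is delegated to
`MASS::isoMDS`. The reported stress is recomputed from the final
configuration as $\sqrt{\sum(d - \hat d)^2 / \sum d^2}$ (a fraction in
$[0,1]$, invariant under rigid motions), and RSQ is the squared Pearson
correlation between disparities and configuration distances. SPSS's ALSCAL
optimizes a different loss (S-stress); its printed stress values are not
comparable and no attempt is made to replicate them. Zero input
dissimilarities are nudged by a relative $10^{-9}$ because nonmetric MDS
requires positive dissimilarities; with fewer points than `k + 1` the
function refuses rather than returning a degenerate embedding.

## The synthetic generator

The generator exists so that every downstream stage has data with *known*
structure:

* **HWE with inbreeding**: each call is identical-by-descent with
  probability `fis` (one allele drawn, duplicated), otherwise two
  independent draws — realizing $P(\text{hom } i) = p_i^2 + f p_i(1-p_i)$,
  $P(\text{het } ij) = 2 p_i p_j (1-f)$. `fis = 0` gives exact HWE;
  `fis = 1` gives all homozygotes.
* **Population structure**: per population and locus, frequencies are drawn
  from the multi-allelic Balding–Nichols distribution, a Dirichlet with
  parameters $p\,(1-F)/F$ around the ancestral vector $p$, then genotypes
  are sampled under HWE. One parameter, $F$, controls divergence and is
  recoverable by the Weir–Cockerham estimator.
* **Anomalies**: off-ladder substitutions and third alleles are injected
  per call at configured rates, with a placement log returned so QC
  reporting can be checked against ground truth.

The default panel mirrors the study the package's fixtures come from: 21
loci, allele counts spanning 7–48, cohort size N = 543, frequencies drawn
once from a symmetric Dirichlet (concentration 1.5, chosen to give the
skewed spectra real STR loci show). Everything is driven by a single
integer seed; identical seeds give identical tables.

**What the synthetic validation shows — and does not.** On generated data
the pipeline demonstrably holds its type-I error (HWE p-values are uniform
under equilibrium; rejection at $\alpha = 0.05$ over 500 replicates at
$B = 1000$, cohort size 543, stays within binomial error), detects strong
inbreeding ($f = 0.3$ rejected in >90% of replicates), and recovers
divergence and tree structure. The generator does not emulate stutter or
allele dropout, genotyping error, stepwise mutation, or family structure;
passing these tests says the *statistics* are computed correctly under
their own assumptions, not that those assumptions hold for any particular
laboratory's data.

## Numerical and design choices

* Frequency tables read from publications are accepted when each locus sums
  to within 0.005 of 1 (they are rounded to 5 decimals in print) and are
  renormalized only on request; internally constructed tables must sum to
  1 within 1e-6.
* Monte-Carlo p-values use the add-one rule everywhere; seeds are part of
  every result row, and the RNG state of the caller is always restored.
* All statistic comparisons in permutation loops carry an absolute 1e-9
  slack toward counting a tie as a hit (conservative direction).
* Distance matrices assert symmetry to 1e-12 and a zero diagonal on
  construction.
* The per-locus summary rounds nothing internally; formatting to the
  conventional 4/5 decimals happens only in the CSV writers.
* Test problem sizes (cohorts of 50–10,000, 500 calibration replicates at
  $B = 1000$, 20-seed recovery runs) were chosen as the smallest sizes at
  which the checked quantities have standard errors well below the asserted
  tolerances.

## Known limitations

* No θ-corrected (subpopulation-adjusted) match probabilities and no
  kinship likelihood ratios beyond TPI.
* No haplotype-frequency estimation; the LD test is a pure association
  screen on genotypes.
* Weir–Cockerham from frequency tables uses HWE-expected heterozygosity;
  with genotype-level data for all populations a fully observed version
  would be preferable.
* No bootstrap support on neighbor-joining trees.
* The generator treats `FIS` as a free parameter; it does not infer
  inbreeding from consanguinity statistics.
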