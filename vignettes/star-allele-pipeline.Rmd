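---
title: "Two-SNP star-allele analysis of SLCO1B1: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-SNP star-allele analysis of SLCO1B1: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcohap)
```

## The two-locus star-allele system

`slcohap` analyzes the two exonic *SLCO1B1* SNPs that carry most of the
gene's clinical pharmacogenetics: c.388A>G (rs2306283) and c.521T>C
(rs4149056). The four possible haplotypes have fixed star names and
function classes:

```{r}
star_allele_table()
```

Both reduced-function alleles (\*5, \*15) — and only they — carry 521C.
That single fact shapes the whole pipeline: the CPIC phenotype (normal /
intermediate / low OATP1B1 function, by the count of reduced-function
alleles in the diplotype) is a function of the unphased c.521 genotype
alone. The package therefore calls headline phenotypes from the 521C
dosage (`phenotype_from_dosage()`), keeps the diplotype route
(`assign_diplotype()` then `phenotype_of()`) for reporting phase, and
tests their equality exhaustively — phase inference can never change a
phenotype call.

## Haplotype frequencies by EM

With unphased genotypes, eight of the nine two-locus genotype classes
determine their haplotype pair; only the double heterozygote
(388 A/G + 521 T/C) is ambiguous between the *cis* pair (\*1a, \*15) and
the *trans* pair (\*1b, \*5). Under random mating the log-likelihood of
the haplotype frequency vector $f = (f_{1a}, f_{1b}, f_5, f_{15})$ is the
multinomial over the nine genotype classes, and the EM algorithm is:

* **E-step** — split the double-heterozygote count $n_{11}$ between the
  phases with weight
  $w = f_{1a} f_{15} / (f_{1a} f_{15} + f_{1b} f_5)$ for the *cis* pair;
  all other classes contribute their forced haplotypes.
* **M-step** — set each $f_h$ to its expected gamete count over $2N$.

Two structural properties follow and are asserted in the tests: the
marginal allele frequencies are conserved exactly at every iterate
($f_{1b} + f_{15}$ equals the observed 388G frequency and
$f_5 + f_{15}$ the observed 521C frequency), and the log-likelihood never
decreases. Because the maximum-likelihood estimate for codominant data
preserves the observed allele frequencies, the likelihood can be
maximized independently along the one remaining degree of freedom
($f_{15}$, bounded by the marginals); the test suite uses a fine grid
search over that segment — plus a coarse full-simplex sweep confirming
the optimum lies on it — as an independent oracle for the EM.

Numerical choices: the default start is the linkage-equilibrium product
of observed allele frequencies ("LE"), making inference fully
deterministic (no RNG anywhere in estimation); convergence is
`max |Δf| < 1e-10` with a cap of 10,000 iterations — far below reporting
precision and cheap at two loci. Degenerate inputs are handled
explicitly: a table whose only occupied class is the double heterozygote
has a flat likelihood ridge and is flagged non-identifiable (with a
warning) rather than iterated; a zero phase denominator with
$n_{11} > 0$ splits 50/50 for that iteration and sets a flag. The double
heterozygote is reported as the most probable phase with its posterior
attached (ties break toward \*1a/\*15, documented and arbitrary) rather
than fractionally assigned; phenotype calls are unaffected by this
choice by construction.

## Allele frequencies and Hardy–Weinberg testing

Frequencies are computed on chromosomes actually observed
(2 × non-missing samples), so every denominator is well defined under
missingness; a sample missing one locus still contributes to the other
locus's counts but is excluded (and tallied) from all two-locus
computations. The minor allele is the strictly second-most-common allele,
with an exact 50/50 tie reported as the cDNA variant allele. One
consequence worth knowing: in a group where the 388G frequency exceeds
0.5, the reported minor allele at c.388 is the ancestral A — published
tables sometimes print the variant-allele frequency in that situation
instead.

Hardy–Weinberg equilibrium is tested with the exact conditional test:
enumerate every heterozygote count of the same parity compatible with the
observed allele counts, and sum the conditional probabilities no larger
than the observed configuration's. This is exact at any sample size,
testable by enumeration, and free of the chi-square approximation's
small-count fragility; the 1-df chi-square goodness-of-fit remains
available behind `method = "chisq"`. Significance follows the
conventional α = 0.05 with no multiple-testing adjustment, matching
standard practice in descriptive frequency studies; p-values are reported
raw.

## Cross-group testing

Count tables are compared with the Pearson chi-square test (no continuity
correction anywhere — the package's concordance checks on reconstructed
published tables only hold without it), the exact two-sided 2×2 Fisher
test (sum of hypergeometric probabilities ≤ the observed table's, with
1e-7 relative slack for float ties), or a Monte-Carlo Fisher test for
larger sparse tables: tables are drawn with both margins fixed
(Patefield's sequential hypergeometric fill via `r2dtable`) and
$\hat p = (1 + \mathrm{hits}) / (B + 1)$ reported with its binomial
standard error, deterministically for a given seed. `select_test()`
chooses among them by the usual expected-count ≥ 5 rule and records the
method used. The 388-vs-521 frequency comparison treats the two loci's
chromosomes as independent samples even though they come from the same
individuals; the result carries an explicit note, since this matches how
such comparisons are commonly (if imperfectly) reported.

## The cohort simulator

`generate_cohort()` draws each individual's haplotype pair from the
group's frequency vector: with probability F (the inbreeding coefficient)
one haplotype is drawn and duplicated — identity by descent, producing
the homozygote excess characteristic of consanguineous populations —
otherwise two independent draws (random mating). Each locus is then
independently set missing at `missing_rate`. One child RNG stream per
group is derived from the root seed (`seed + 1000003 × group index`, mod
2³¹−1), so appending a group never perturbs earlier groups' draws, and
the draw order within a stream is fixed. Outputs (VCF v4.2 with REF =
ancestral and ALT = variant allele, metadata TSV, truth JSON) are
byte-deterministic.

Two presets reproduce the structure of a published Qatari cohort of 1050
exomes (Bedouin/Arab 587, Persian/South Asian 387, African 76). They
exist in duplicate because that study's published haplotype-frequency
rows and MAF rows are mutually inconsistent: the haplotype percentages
imply a pooled 388G frequency near 0.73 and 521C near 0.42, while the
printed MAFs on the same cohort are 0.49 and 0.24 — and the phenotype
counts are exactly consistent with the MAFs, not the haplotype rows. The
package does not adjudicate: `"hf-table"` uses the printed per-group
haplotype frequencies as truth, `"maf-consistent"` uses per-group
frequencies consistent with the printed MAFs, and callers must name one.
For `"maf-consistent"` the MAF pair fixes only two of the three free
parameters; the remaining degree of freedom is closed by assuming linkage
equilibrium (each $f$ a product of allele frequencies). The phenotype
distribution depends only on the 521C marginal, so this closure does not
affect phenotype truth. Both presets default to F = 0 and no
missingness: the published cohort's mild low-function excess is
consistent with consanguinity, but no F value is stated or estimable from
the printed tables, so nonzero F is left to the user.

What the simulator emulates: group sizes, per-group haplotype
frequencies, random mating or uniform inbreeding, uninformative
missingness. What it does not: genotyping error, admixed individuals,
related samples beyond the single-F model, coverage-dependent
missingness, or any linkage to variants outside the two-SNP system.
Passing parameter-recovery tests on simulated cohorts therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real-data artifacts upstream of the VCF.

## Reconstructing published tables

Published frequency tables print percentages over known denominators, so
the underlying integer counts are exactly recoverable:
`reconstruct_counts()` rounds `p × N / 100` to the nearest integer (half
away from zero) and reports residuals. A genuine printed cell lands
within ~0.06 of an integer at these denominators; the one known
exception in the reference tables is the African intermediate phenotype
cell, printed as 7.11% where the column arithmetic forces 13/76 =
17.11%. The package flags that cell (residual 7.6) and always derives
intermediate counts by subtraction from the group size, never from the
printed value. `check_reference_tables()` verifies the full identity set
— pooled phenotype and haplotype percentages against the printed totals,
and the phenotype-implied 521C frequencies against the printed MAFs — and
is exposed as the `check-tables` command.

Display rounding is fixed at 2 decimals for frequencies and percentages
and 4 for p-values, mirroring the published tables; JSON reports carry
full precision. Problem sizes used in the test suite are chosen to keep
the whole suite fast while leaving no estimator untested at realistic
scale: exhaustive oracle sweeps to N ≤ 24 (Fisher) and n ≤ 50 (HWE),
100 random tables for the EM-vs-grid check, and 20 replicate cohorts of
5000 samples per group for parameter recovery.

## Known limitations

* Exactly two biallelic autosomal loci; no rarer *SLCO1B1* alleles
  (\*14, \*17, …), no multi-allelic or X-linked handling, and no
  "increased function" phenotype class, which would need alleles outside
  this system.
* Phase is inferred statistically, never from reads; individual diplotype
  calls for double heterozygotes are posterior-weighted guesses, and only
  cohort-level frequencies are maximum-likelihood quantities.
* The r×c exact test is Monte-Carlo, not the Freeman–Halton network
  algorithm; its p-values carry a reported simulation error.
* Ancestry group labels are an input; the package performs no ancestry
  inference.
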