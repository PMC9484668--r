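---
title: "Estimating carrier prevalence of rare recessive variants from aggregate allele counts"
author: "CarrierFreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carrier prevalence of rare recessive variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CarrierFreq)
```

## The problem

For a recessive monogenic disease — congenital leptin deficiency caused by
biallelic deleterious *LEP* variants is the motivating case — the clinically
relevant questions are: how many people carry one pathogenic allele of the
gene, and how many carry two (either the same variant twice, or two
different ones: a compound heterozygote, functionally equivalent to a
homozygote)? Individual-level genotypes for such rare variants are not
publicly available, but aggregate allele counts per variant and population
stratum are, through reference databases such as gnomAD. CarrierFreq turns
such a table into carrier-prevalence estimates, with the variant set chosen
by a consensus over categorical in silico pathogenicity predictors.

## The model

Let a gene have pathogenic variants $i = 1, \dots, m$ with allele
frequencies $q_i = \mathrm{AC}_i / \mathrm{AN}_i$ in a stratum, and let
$q = \sum_i q_i$, $p = 1 - q$. Under Hardy–Weinberg equilibrium — random
mating, no selection, migration or drift — and the single-locus assumption
that a chromosome carries at most one pathogenic variant of the gene,
genotype frequencies satisfy $p^2 + 2pq + q^2 = 1$, and:

* heterozygous carriers: $P_\text{het} = 2pq$,
* homozygous **including** compound heterozygous: $P_{\text{hom+CH}} = q^2$,
* strictly homozygous: $P_\text{hom} = \sum_i q_i^2$,
* compound heterozygous: $P_\text{CH} = q^2 - \sum_i q_i^2 \ge 0$
  (Cauchy–Schwarz; zero when at most one variant has $q_i > 0$).

Two numerical choices matter at the margins. First, we use $p = 1 - q$
inside $2pq$ rather than the rare-variant approximation $p \approx 1$; for
the worked example's $q = 230/282{,}912$ the exact form gives a reciprocal
of 615.5 (rendered "1: 616") where $2q$ alone gives 615.1. Second, a
stratum with zero pathogenic variants yields `NA` components, not zero: an
absence of qualifying variants in a 5,000-person stratum is not evidence of
zero risk.

The compound-heterozygote subtraction is exact only under the single-locus
allele model; `simulateGenotypes()` implements exactly that model (each
chromosome carries variant $i$ with probability $q_i$, else reference), and
the test suite checks the closed forms against exhaustive enumeration of
ordered allele pairs, so the formulas and the simulator are verified against
each other by construction. Real chromosomes can in principle carry two
variants in *cis*, which would shift true compound heterozygosity below the
estimate; with every $q_i \lesssim 10^{-4}$ the effect is negligible
relative to the sampling noise of the allele counts themselves.

## The consensus pathogenicity rule

Five categorical predictors are consumed as data (their execution is out of
scope): SIFT (`tolerated`/`deleterious`), PolyPhen2 (`benign`/
`possibly_damaging`/`probably_damaging`), MutationTaster2021
(`benign`/`deleterious`), FATHMM-MKL and PROVEAN (`neutral`/`damaging`).
A variant is called pathogenic by `PathogenicityDefinition(minTools = k)`
when at least $k$ predictors make a damaging-side call. Both PolyPhen2
damaging grades count as damaging: the tallies a $k$-of-$n$ rule consumes
are over any damaging-side call, and dropping the "possibly" grade cannot
reproduce the worked example's 32-variant set at $k = 2$.

Three overlays modify the rule:

* **HC LoF** (`hcLofIsPathogenic`, default `TRUE`): high-confidence
  loss-of-function variants are pathogenic whenever $k \ge 1$. Of the five
  predictors only MutationTaster2021 scores non-missense variants, so LoF
  variants can never reach $k \ge 2$ by tool count alone; the LOFTEE-style
  confidence label substitutes for the missing predictors. The source rule
  is stated for the $k = 2$ definition; extending it to every $k \ge 1$ is
  this package's choice, switchable off.
* **Evidence modes** (`tools_or_clinical`, `tools_or_functional`,
  `tools_or_any_evidence`): a variant with a literature-evidence flag is
  pathogenic regardless of tool count. Evidence only ever enlarges the
  pathogenic set.
* **ClinVar** (`clinvarMode`, default `report_only`): the ClinVar category
  is carried through but does not change verdicts — a variant called
  damaging by all five tools and supported by clinical case reports keeps
  its pathogenic call even against a ClinVar "benign" assertion.
  `veto_benign` is available for sensitivity analyses and suppresses only
  the tools-only route, never the LoF or evidence routes.

`minTools = 0` is an accounting rule (every variant pathogenic-side), used
for the "all variants regardless of pathogenicity" row of the definition
sweep.

```{r sweep}
tab <- readVariantTable(system.file("extdata",
  "lep_gnomad_all_synthetic.tsv", package = "CarrierFreq"))
renderTables(thresholdSweep(tab, 0:3))[, c("definition", "n_variants",
  "het_carriers", "ratio_het", "ratio_hom_incl_ch")]
```

## The worked-example table

`inst/extdata/lep_gnomad_all_synthetic.tsv` is a 75-variant table for the
leptin gene across all populations (141,456 individuals, so
$\mathrm{AN} = 282{,}912$ everywhere). Its *group-level* tallies — 68
non-synonymous plus 7 LoF variants; 22/53/32/19 variants at tool-count
thresholds 0/≥1/≥2/≥3 (the ≥2 and ≥3 sets including the five
high-confidence LoF variants); carrier totals 2,486 het + 105 hom overall
and 230/67/32 in the pathogenic sets; the common polymorphism rs17151919 at
AC = 2,377 with 105 homozygotes — reproduce the published gene-level counts
exactly. The *per-variant* allocation of allele counts within each group is
synthetic (hence the file name): the real per-variant spreadsheet is not
shipped. Consequently all quantities that depend only on group sums
($q$, $2pq$, $q^2$) are exact reproductions, while $\sum q_i^2$-based
columns are allocation-dependent and are treated as approximate.

Setting $\mathrm{AN} = 2N$ for every variant assumes every individual was
successfully genotyped at every site. Real gnomAD AN values vary per site
with coverage; the printed gene-level numbers are consistent with the
$2N$ convention, which is why the fixtures adopt it. `aggregateStrata()`
derives `ALL` rows by summation when only per-population or per-sex rows
are present, so the same estimation code serves any stratification.

## The synthetic cohort generator

`generateCohort(CohortConfig(...))` emulates the structure of a gnomAD
gene export with known ground truth:

* **Frequency spectrum**: a configurable mix of singletons
  ($q_i = 1/2N$), rare variants (log-uniform between $1/2N$ and the lower
  common bound) and common polymorphisms (uniform in `commonAfRange`).
  Defaults (60% singletons, 5% common) mimic the observed dominance of
  singletons in rare-disease gene exports.
* **Genotype counts**: per population, genotype counts are drawn
  multinomially from $(p^2, 2pq, q^2)$, so generated `ac`/`nhom` pairs are
  HWE-consistent within each population and allele-count variance matches
  binomial sampling. An `exactCounts` switch emits deterministic
  $\mathrm{round}(2Nq_i)$ counts for fixture building.
* **Predictor calls**: drawn per tool conditional on the latent
  pathogenicity label with configurable sensitivity/specificity (defaults
  0.85/0.80, reflecting the characterisation of these tools as sensitive
  but unspecific). LoF-class variants (fraction `lofFraction`) receive a
  MutationTaster2021 call only, plus a confidence label — `HC` when truly
  pathogenic, `LC` otherwise. That deterministic link is a simplification
  (real LoF-confidence filters flag annotation artifacts, not
  pathogenicity); it makes noiseless-recovery tests exact.
* **Determinism**: every stage draws from a substream seeded as
  `seed + {0,1,2}`, so tables are pure functions of the config and partial
  re-draws stay aligned.

What the generator does **not** emulate: coalescent site-frequency spectra,
linkage and phasing, per-site coverage variation in AN, and correlated
errors between predictors (real tools share training data and features, so
five calls are far from independent; the simulator's independence
assumption makes consensus recovery look better than it would be on real
annotations). Passing recovery tests therefore validate the arithmetic and
the pipeline plumbing, not the real-world accuracy of any predictor
ensemble.

Validation problem sizes used by the tests and the acceptance script —
genotype simulations at $n = 10^5$ individuals, cohorts of 300–2,000
variants, Wahlund cohorts of $2 \times 25{,}000$ — were chosen so every
binomial 3-standard-error check has comfortable resolution while the whole
suite runs in seconds.

## Hardy–Weinberg consistency and the Wahlund effect

`hweConsistencyCheck()` compares observed genotype counts of one variant
with HWE expectations at $\hat q = \mathrm{AC}/\mathrm{AN}$ via a
chi-square statistic (1 free df once $\hat q$ is estimated from the same
counts). Two situations make it fire:

```{r hwe}
# a common variant pooled across populations with very different q:
# 105 observed homozygotes against ~10 expected
unlist(hweConsistencyCheck(ac = 2377, an = 282912, nhom = 105,
                           sampleSize = 141456))
```

This is the Wahlund effect: pooling subpopulations with different allele
frequencies inflates homozygotes relative to the pooled-frequency HWE
expectation (here, rs17151919 at 8.4% frequency in the
African-American stratum against ~0.04% elsewhere). `wahlundCohort()`
reproduces the phenomenon from first principles — within-subpopulation HWE
simulation, then pooling — and the check flags the pooled row while
leaving well-mixed cohorts unflagged. Aggregate estimates that include
such common benign variants (the $k = 0$ accounting rows) therefore
violate HWE; the pathogenic sets at $k \ge 1$ consist of rare variants for
which the effect is negligible.

## Rounding and reporting

Published prevalence tables mix rounding conventions (integer below
1,000, two to four significant figures above). `formatPrevalenceRatio()`
therefore exposes the mode per call: `"integer"`, `"sigfigs"` with a
figure count, and a `"paper"` default (integer below 1,000, else 3
significant figures). Report tables always carry both the raw probability
and the "1: N" rendering, and `NA` estimates render as `"NA"`, never as a
ratio.

## Known limitations

* Point estimates only: no confidence intervals on prevalence (the allele
  counts would support binomial intervals; out of scope by design).
* Autosomal biallelic model only: no X-linked ploidy, no inbreeding
  coefficient, no exact HWE tests beyond the chi-square check.
* The classifier consumes predictor output as given; it cannot correct
  systematic predictor bias, and the definition sweep shows how strongly
  the estimate depends on the chosen threshold (a factor of ~40 between
  $k = 0$ and $k = 3$ in the worked example).
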