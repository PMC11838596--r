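---
title: "Comparing interval- and SNP-level local ancestry calls, and mapping with them"
author: "laconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing interval- and SNP-level local ancestry calls, and mapping with them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laconcord)
```

## The problem

Admixed cohorts — Hispanic/Latino populations being the motivating case —
carry genomes that are mosaics of segments inherited from distinct
ancestral populations (here labeled African, Amerindian and European,
optionally extended to seven continental groups). *Local ancestry* is the
ancestral origin of a segment on one chromosome copy; at any locus an
individual carries a diploid count of 0, 1 or 2 copies of each ancestry,
and the counts sum to 2. *Global ancestry* is the genome-wide average of
those counts.

Local ancestry is not observed: it is inferred against external reference
panels, and different inference generations produce different call sets.
A typical situation is an older inference that reports diploid counts
over genomic *intervals* on one genome build, and a newer inference that
reports calls at every *SNP* on a newer build, with its own reference
panel, QC fields (MAF, imputation R2) and possibly extra ancestries.
Before re-using or replacing the older calls, one wants to know: do the
two channels agree globally and locally, where do they disagree, do the
disagreements concentrate in genomic territory known to be problematic
(ENCODE-blacklist-style regions, gene clusters), and do downstream
admixture-mapping associations replicate across the channels?

`laconcord` implements that comparison pipeline as reusable, tested
components, together with a synthetic-cohort generator so that every
stage can be exercised and validated without access-restricted cohort
data.

## The synthetic cohort

The generator is a first-class module, not a test fixture. It emulates
the *statistical structure* of the real comparison:

* **Global proportions.** Each individual belongs to a "genetic analysis
  group" (Mainland-, Caribbean- and Cuban-like by default) and draws a
  proportion vector from a group-specific Dirichlet prior. The default
  alphas give roughly 5–25% African, 5–45% Amerindian and 50–80%
  European ancestry with realistic between-individual spread.
* **Tracts.** Each haplotype is a realization of the standard
  Poisson-switch ("pool") model of admixture: switch points arrive along
  the genetic map as a Poisson process with rate $g$ per Morgan
  ($g$ = generations since admixture, default 10, a conventional value
  for Hispanic/Latino admixture timing), and at each switch the ancestry
  is redrawn from the individual's own proportion vector,
  self-transitions allowed. Consequently inter-switch tract lengths are
  Exponential($g$) in Morgans and the per-site ancestry distribution is
  stationary at the individual's proportions — both properties are
  asserted by the test suite. Switches with self-transition are retained
  as separate tracts precisely so the exponential law holds exactly.
* **Two observation channels.** The interval channel tiles each
  chromosome (default width 200 kb, the scale of interval-based call
  sets) and records, per haplotype, the majority-by-length ancestry in
  each interval, ties broken deterministically toward the lowest
  ancestry index. The SNP channel samples a position grid (default 20 kb
  spacing; the real SNP sets are denser, but the ratio of many SNPs per
  interval is what matters for matching) and reads the true ancestry at
  each point. Each channel then passes through a miscall model: with a
  per-locus probability, a haplotype's call is replaced by a uniform
  draw over the other $K-1$ ancestries. Declared *problem regions*
  inflate the miscall rate locally — this is the mechanism that lets the
  enrichment analysis be validated end-to-end. The SNP channel can
  additionally apply a row-stochastic *leak matrix* before the miscall
  step, modeling systematic relabeling such as European calls being
  attributed to a Middle Eastern reference when extra panels are added.
* **Two coordinate systems.** SNP positions are shifted by
  `build_shift_bp` relative to the interval build; a block liftover map
  (a monotone stand-in for an assembly chain file) carries the interval
  channel onto the SNP build. Block boundaries are deliberately placed
  mid-interval so the "mapped into more than one region" discard rule is
  exercised, and a block can be redirected to another chromosome to
  exercise the cross-chromosome discard.
* **Phenotype.** A quantitative trait
  $y = X\beta + \gamma\, g_{\text{true}} + u_{\text{household}} +
  u_{\text{block}} + a + \varepsilon$, where $g_{\text{true}}$ is the
  *true* diploid count of a causal ancestry at a causal locus, the
  covariates mimic a population-cohort design (age, sex, center, genetic
  analysis group, eGFR, five genetic PCs), households and census blocks
  are nested grouping factors, and $a$ is a polygenic term with
  covariance $\sigma^2_{\text{kin}}\, 2\Phi$ built from a block-diagonal
  sib-pair kinship matrix ($\Phi_{ij} = 0.25$ within pairs). Sib pairs
  are drawn independently of household membership so the kinship and
  household components remain separately identifiable.

All randomness flows from a single config seed; each stage derives its
own substream deterministically, so a fixture set rewritten with the same
seed is byte-identical (checked via MD5 in the manifest).

What the generator does **not** emulate: genotype sequences, LD beyond
the ancestry-tract process, reference-panel construction, realistic
miscall structure of any specific inference tool (the rates are free
parameters, as nothing published calibrates them), or X-chromosome
inheritance. Passing tests therefore demonstrate correctness of the
*pipeline computations* under a faithful admixture model, not accuracy
claims about any particular inference method on real data.

## Global ancestry

Two estimators, one per channel:

* interval channel: length-weighted counts,
  $\pi_k = \sum_i \ell_i c_{ik} \big/ 2\sum_i \ell_i$;
* SNP channel: equally weighted, $\pi_k = \tfrac{1}{2}\,\overline{c_k}$.

Rows sum to 1 automatically because diploid counts sum to 2.
`compare_global()` reports per-ancestry Pearson correlations across
individuals plus the mean signed difference, which exposes systematic
shifts (one channel assigning uniformly lower European ancestry, say)
that a correlation alone hides. Globals are computed post-QC by default;
nothing in the algebra depends on that choice and the filter thresholds
are arguments.

## Local concordance

Intervals are lifted to the SNP build first; intervals spanning more than
one liftover block, mapping to a different chromosome, or covered by no
block are discarded and reported with their original coordinates. A SNP
matches an interval when `start <= pos <= end` (closed on both ends; when
abutting intervals share a boundary coordinate the earlier interval
wins — a deterministic tie-break that non-overlapping interval sets make
essentially moot). For each matched pair and each shared ancestry, the
Pearson correlation of the diploid counts across individuals is the unit
of comparison. Correlations are undefined when either vector is constant
(e.g. a locus fixed for one ancestry); these are recorded and excluded
from means and standard deviations — the standard convention.

A pair is *flagged* when its correlation falls below 0.9 in **any**
considered ancestry; flagged pairs are merged into disjoint genomic
regions (overlapping or adjacent interval spans are unioned). The
genome summary reports unweighted per-pair means and SDs; a SNP-dense
interval therefore contributes many pairs, which matches how the pair
counts are reported in the comparison this package operationalizes.

## Annotation enrichment

Local ancestry has extremely long-range LD, so a discordant pair is
credited to an annotation class when it lies within 0.5 Mb of any
interval of that class (edge-to-edge gap; overlap is distance zero;
different chromosomes are infinitely far; a query exactly at 0.5 Mb is
assigned, one base farther is not). The contrast group is a uniform
random sample, of the same size as the flagged set, from pairs with
correlation above 0.97 in *all* considered ancestries. Controls are
sampled at the pair level: the published account mixes "regions" and
pair counts, and pair-level sampling is the reproducible reading — the
ambiguity is documented rather than hidden. Percentages per class use
the group's mapped count as denominator (classes may jointly exceed
100% because they overlap); the overall mapped percentage uses the
group size. A 2x2 Fisher exact test is available as a convenience.

## Admixture mapping

The null model is fitted once per trait by REML:
$y = X\beta + u_{\text{household}} + u_{\text{block}} + a + \varepsilon$,
with $\mathrm{Var}(y) = V = \sigma^2_h Z_h Z_h^\top + \sigma^2_b Z_b
Z_b^\top + \sigma^2_{\text{kin}} 2\Phi + \sigma^2_e I$. Every locus is
then a score test: $U = g^\top V^{-1}(y - X\hat\beta)$,
$\mathrm{Var}(U) = g^\top P g$ with
$P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}$, and
$U^2/\mathrm{Var}(U) \sim \chi^2_1$. The projection $P$ is formed once
and reused across all loci and ancestries, which makes genome scans a
few dense matrix products.

Numerical choices:

* The restricted likelihood is maximized by L-BFGS-B over the variance
  components with non-negativity bounds. When every random effect is a
  grouping factor the likelihood is evaluated through the low-rank
  (Woodbury) identity in the factor dimension, $O(nq^2)$ instead of
  $O(n^3)$; a dense kinship matrix switches to Cholesky factorization of
  the full covariance. The two paths agree to optimizer precision (the
  suite cross-checks the factor path against lme4 on a shared model).
* Components estimated at the zero boundary (below `drop_tol` times the
  phenotypic variance) are dropped and the model refit — standard
  boundary handling.
* A locus whose counts are constant or lie in the covariate span has
  score variance zero; it is flagged untestable and its p-value is
  missing rather than spuriously extreme. The tolerance is relative to
  the centered sum of squares of the counts, so real loci (whose score
  variance is of the same order) are never misclassified.
* Rank-deficient covariate matrices and non-PSD kinship matrices are
  rejected up front with the offending columns named.

Tested ancestries default to African and Amerindian — the ancestries
whose frequency differentials drive admixture-mapping signals in
Hispanic/Latino cohorts — with European available by argument. A
7-ancestry call set is first collapsed to the three majors plus a
combined "other" (`collapse_ancestries()`); the collapse cannot change
the African or Amerindian tests, which the suite asserts.

Two simplified multiple-testing substitutes are provided in place of a
full test-statistic-process calibration (a separate published method,
out of scope here):

* `bonferroni_effective`: walk each chromosome and count a locus as
  opening a new independent block when its count correlation with the
  previous block-opening locus falls below 0.1; the threshold is
  $\alpha / M_{\text{eff}}$ summed over tested ancestries.
* `permutation`: permute the null-model marginal residuals $B$ times,
  rescan, and take the $\alpha$-quantile of the per-permutation minimum
  p-value. In the complete-dependence limit (duplicated loci) this
  returns $\alpha$ itself, and for independent loci it agrees with the
  Bonferroni estimate to within Monte-Carlo error — both limits are in
  the test suite.

`compare_top_hits()` builds the discovery/replication table: per genomic
region and per scan (channel x batch), the locus with minimum p, ties
broken by position, regions with only untestable loci flagged rather
than silently dropped.

## Design decisions worth recording

* **Coordinates.** All in-memory coordinates are 1-based and closed,
  the native convention of the R/Bioconductor interval stack used for
  the arithmetic (GRanges); BED's 0-based half-open convention is
  confined to the rtracklayer boundary, and interval TSV/VCF positions
  are 1-based on disk. Keeping one in-memory convention removes a whole
  class of off-by-one errors at the cost of one documented conversion.
* **Genotyped variants and QC.** Variants with missing imputation R2
  are treated as directly genotyped and exempt from the R2 filter; the
  MAF filter always applies. The stricter R2 = 0.95 re-run is the same
  code path with a different argument.
* **Calibration checks use independent loci.** The null-calibration
  test draws each locus independently as Binomial(2, $\pi$) with a
  proportion vector common to all individuals, rather than from the
  tract process, because the uniformity diagnostics (empirical size,
  Kolmogorov–Smirnov) presume independent tests: tract-process loci
  share massive LD by design, and even conditionally independent loci
  correlate across individuals through global ancestry when proportions
  vary. This is a property of the calibration experiment, not of the
  scan code, which is identical in both settings.
* **Localization check.** The cross-channel concordance experiment uses
  cohorts of 500 individuals on two chromosomes (60 and 50 Mb), an
  ancestry effect of 0.5 residual SD per count, and merges loci with
  p below 1e-3 (padded by 1 Mb) into candidate regions before asking
  whether both channels' minima share a region. The padding is of the
  order of the tract-LD scale; the threshold is a region-building
  device, not a significance claim.
* **Problem sizes.** The shipped tests run the null calibration at
  n = 1000 individuals x 2000 loci, variance-component recovery at
  n = 2000 x 50 replicates, tract-law checks at ~6000 tracts, and the
  concordance/enrichment simulations at 150–500 individuals on two
  chromosomes of 50–60 Mb — sizes chosen so the full suite completes on
  a laptop-class single core while keeping every Monte-Carlo band at
  three standard errors or better.

## Known limitations

* The miscall model is symmetric and locus-independent apart from the
  problem-region inflation; real inference errors are haplotype- and
  panel-structured.
* The effective-loci Bonferroni estimator is greedy and first-order; it
  brackets, but does not reproduce, a full process-level threshold.
* The permutation threshold permutes marginal residuals, which ignores
  the (small, at these variance-component magnitudes) correlation
  structure the null model removes.
* Interval-channel majority calls lose sub-interval switch information
  by construction; with tract lengths near the interval width the two
  channels disagree for physical rather than inferential reasons, and
  the concordance limits in the tests are stated for tract lengths well
  above the interval width.
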