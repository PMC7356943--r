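---
title: "Methods: data-driven genetic risk scores, family-level microbiome statistics, and gene-microbiome interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven genetic risk scores, family-level microbiome statistics, and gene-microbiome interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microgrs` implements an analysis pipeline linking host genetics and the gut
microbiome to adiposity: a data-driven genetic risk score (GRS) built from
per-SNP nonparametric genotype/BMI tests, family-level 16S statistics
(normalization, diversity, three differential-abundance routes), and
sex-stratified taxon-by-GRS interaction regressions. Because subject-level
genotypes and phenotypes from studies of this design are rarely public, the
package ships a synthetic cohort generator that emulates the statistical
structure such analyses assume; every downstream stage is exercised and
tested against it.

## The genetic risk score

The GRS is *data driven*: rather than importing published effect alleles, it
learns, per SNP, which genotype categories carry higher BMI in the cohort at
hand, in three stages.

1. **Screen.** For each biallelic SNP the three genotype groups (no copies,
   one copy, two copies of the minor allele) are compared on BMI with a
   tie-corrected Kruskal-Wallis test; SNPs with `p < 0.20` continue. The
   deliberately liberal threshold admits marginal candidates that the later
   confirmatory stage can still reject.
2. **Code.** Genotype groups are ordered by median BMI and pairwise
   Mann-Whitney post-hoc tests decide which adjacent groups are
   distinguishable. Groups with similar effects (pairwise `p >= 0.05`) are
   merged, yielding a binary partition whose higher-median side is the
   *risk* category. This reproduces the characteristic mixed coding shapes
   of obesity loci: dominant (`TT` vs `AA+TA`), recessive (`AA+AG` vs `GG`)
   and heterozygote codings (`AG` vs `GG+AA`).
3. **Confirm and filter.** The binary coding is re-tested (Mann-Whitney,
   `p < 0.10`); codings with fewer than 10% of genotyped subjects in either
   category are dropped (*low-count*), as is the worse member of any pair of
   codings whose 0/1 indicators correlate beyond `|r| = 0.8`
   (*collinearity*).

The score is the **per-locus indicator sum**: one point per retained locus at
which the subject's genotype lies in the risk category, so the maximum score
equals the number of retained loci. A subject with risk genotypes at 6 of 10
loci scores 6 - even if homozygous at all six - which distinguishes this
scoring rule from allele counting (which would give up to 12). Subjects are
split into low/high genetic risk at the population mean, ties going to the
high group.

Three decisions here were genuinely open and are fixed as follows. Ordering
and merging use the *median* (not the mean), for coherence with the rank
tests that drive the selection. When the pairwise post-hocs fail to single
out one cut - either all three groups are mutually distinguishable or all
pairs are similar - the median-ordered binary split with the stronger
two-group Mann-Whitney separation is chosen; excluding every
all-pairs-similar SNP instead would discard most marginal stage-1 passers
and empty the funnel, which contradicts how liberal the stage-1 threshold
is. Only SNPs whose groups are literally indistinguishable (best split
`p = 1`) are excluded at stage 2. Finally, subjects missing a genotype at
any retained locus are excluded from the score entirely; no imputation.

A caveat the synthetic experiments make visible: stage 3 tests a partition
that was *chosen to maximize the BMI contrast*, so its null rejection rate
exceeds the nominal 10% and null loci do get retained alongside true ones
(the workflow's selection report shows both). The constructed score is
therefore a noisy, rescaled version of the true genetic burden - exactly as
it would be on real data - and interaction coefficients fitted against the
constructed score are attenuated relative to the planted value. Parameter
recovery is asserted against the planted score; the workflow reports both.

## Microbiome statistics

**Normalization.** Relative abundances are on the 0-100 percent scale
(interaction models evaluate the focal family at 5 and 15). Cumulative sum
scaling (CSS) divides each sample's counts by the sum of its counts up to a
chosen quantile of its nonzero-count distribution, then rescales by the
median factor; with quantile 1 it collapses to total-sum scaling. The
`"auto"` quantile tracks, over a quantile grid, the median absolute
deviation of per-sample quantiles from their across-sample median and stops
at the first grid point where that curve becomes unstable (relative change
above 0.1), falling back to 0.5 - the stability heuristic of the CSS
method, implemented from its description.

**Diversity.** Shannon entropy is in nats (some tools use log2), Chao1 uses
the bias-corrected estimator `S_obs + F1(F1-1)/(2(F2+1))` so samples with no
doubletons are defined, and Bray-Curtis dissimilarity is exposed for
ordination; Shannon and Bray-Curtis delegate to vegan. Diversity-trait
associations are tie-corrected Spearman correlations, overall and within
sex strata.

**Differential abundance** runs three complementary routes, mirroring the
practice of triangulating a biomarker across methods:

- *LDA effect size (LEfSe-style two-class core).* A Kruskal-Wallis screen at
  0.05; features rescaled to one million per sample; over 30 stratified
  bootstrap rounds the one-dimensional discriminant effect - the class-mean
  difference along the feature's axis - is averaged, and the score is
  `log10(10 + |effect|/2)`, thresholded at 2.0. The published tool's
  subclass (within-group Wilcoxon) stage and its exact bootstrap scheme are
  not part of this core: the analyses here are plain two-group comparisons,
  so the subclass stage has nothing to act on. In one dimension the
  discriminant axis is the feature axis itself, which makes the
  within-class covariance inversion trivial; a `1e-6` x mean-variance ridge
  guards degenerate zero-variance features.
- *Zero-inflated Gaussian (ZIG) regression.* Per family, a mixture of a
  point mass at zero whose weight follows a logistic model on log library
  size (depth-dependent dropout: shallow samples have more technical
  zeros) and a Gaussian on `log2(CSS + 1)` with a group mean shift, fitted
  by EM to a log-likelihood tolerance of `1e-8` (max 100 iterations; the
  trace is retained and tested for monotonicity). The group coefficient is
  z-tested with weights from the posterior non-zero membership, and
  q-values are Benjamini-Hochberg across families. The zero model uses log
  library size only - the method's core idea - without moderated variance
  shrinkage; on zero-free data the fit collapses exactly to a pooled
  two-sample z-test, which the tests assert to `1e-6`.
- *Random-forest importance.* Ten repeats of a 500-tree forest on
  stratified 70% training splits; importance is the unscaled out-of-bag
  permutation mean decrease in accuracy (MDA), averaged across repeats;
  each repeat's 30% holdout yields a ROC AUC (tie-aware rank statistic)
  as validation. Both out-of-bag validation and the 70/30 holdout are
  used: MDA comes from the former, AUC from the latter.

## Interaction models

The confirmatory model is ordinary least squares:

`BMI ~ family + GRS + family:GRS + age + METs + energy (+ sex)`

fitted for the pooled cohort and separately for men and women; the sex term
is dropped in stratified fits. The family term is percent relative
abundance. Coefficient standard errors use the unbiased residual variance;
the package reports R-squared, adjusted R-squared and the overall F test.
Predicted-BMI curves evaluate the fit at 5% and 15% family abundance over
the integer GRS range with the remaining covariates held at their stratum
means (the conditioning is not prescribed anywhere, so stratum means are
the documented choice); the slope gap between the two curves is exactly
`10 x` the interaction coefficient per GRS unit.

WHO BMI classes use standard half-open intervals - normal weight below 25,
overweight `[25, 30)`, obese at and above 30 - because the printed cutoff
phrasing ("< 24.9", "< 29.9", "> 30") leaves gaps at the boundaries; the
binary split merges overweight and obese.

## The synthetic cohort generator

The generator is the package's study stand-in, not a tuning dial: its
defaults are fixed at the reference study's printed conditions wherever one
exists, and at one-time documented choices elsewhere.

- **Cohort**: 360 subjects, 70% women (251/360); age 44.8 (SD 10) years,
  physical activity 25.3 (SD 15) METs, energy 2907 (SD 900) kcal, clipped
  at plausibility bounds (18 years, 0 METs, 500 kcal).
- **Genotypes**: 95 independent biallelic SNPs in Hardy-Weinberg
  equilibrium (no linkage disequilibrium). Ten loci are truly
  BMI-associated under mixed dominance patterns with per-category effects
  of 1.3-1.6 kg/m2, matching the 1-2 kg/m2 genotype-group contrasts
  typical of single obesity loci; no per-SNP effect sizes are published,
  so these magnitudes are defaults, not ground truth.
- **Microbiome**: 64 families with power-law rank abundances
  (`rank^-1.1`), log-normal noise (log-SD 1), zero-inflation rising
  linearly from 0 to 0.7 with rarity, and negative-binomial library sizes
  (mean 50,000, floored at 1,000 - the depth threshold below which real
  samples would be discarded). The focal family sits at rank 3 (about 8%
  mean abundance, log-SD 0.5) and is shifted twofold upward in
  high-genetic-risk subjects, spanning roughly the 5-15% window at which
  the interaction models are evaluated.
- **BMI**: baseline 25.9 kg/m2 plus the planted SNP effects, plus a
  sex-specific interaction `beta_sex x (focal abundance x planted GRS)`
  with `beta_female = 0.10` (the women-stratum estimate the package's
  acceptance checks recover) and `beta_male = 0` - the published men
  estimate (-0.006, SE 0.06, p = 0.93) is statistically indistinguishable
  from zero, so the generator plants the null - plus Gaussian noise
  (SD 3). The baseline is calibrated so the default cohort lands near the
  reference marginals: mean BMI 30.0, WHO classes roughly 23/35/42%
  (target 18/30/52%), mean planted GRS 6.0.

What the generator deliberately does **not** emulate: linkage
disequilibrium and population structure, compositional interactions between
families (families are independent given the library size), diet beyond
total energy, raw 16S reads and the upstream bioinformatics
(OTU picking, taxonomy), and any diversity-trait coupling (Shannon-BMI
associations in synthetic cohorts are null). Passing tests therefore
demonstrate that the *statistical machinery* is correct and calibrated
under the assumed generating model - not that the biological findings of
any particular cohort generalize.

## Numerical choices

- Rank tests (Kruskal-Wallis, Mann-Whitney, Spearman) use midranks with tie
  correction and two-sided p-values throughout. For small samples (n <= 9;
  n <= 8 for Spearman) the exact permutation distribution is enumerated,
  with a `1e-9` guard when counting statistics at least as extreme, so the
  implementation reproduces brute-force enumeration to machine precision;
  otherwise the tie-corrected chi-square / normal-without-continuity /
  t approximations apply, chosen so the two-group Kruskal-Wallis and
  Mann-Whitney p-values coincide.
- The Mann-Whitney two-sided p is the permutation mass of `|U - E[U]|` at
  least as large as observed (no continuity correction), which is what
  makes the two-group equivalence above exact rather than approximate.
- ZIG EM: posterior weights initialize at 0.5 for zero cells; the Gaussian
  variance is floored at `1e-12` and the logistic zero model falls back to
  a constant rate if the quasibinomial fit fails; standard errors divide by
  the effective sample size `sum(w) - p`.
- Ties in the collinearity filter (equal stage-3 p) drop the later SNP in
  input order; mean-split ties go to the high group; both are documented
  contracts, and the whole selection is invariant to subject and SNP
  permutations of the input.
- Degenerate inputs are contracts, not crashes: all-missing SNPs are
  flagged untestable, all-zero families are skipped with a flag, constant
  responses give `p = 1` under the tie-corrected convention, zero-library
  samples and non-integer Chao1 inputs raise informative errors.

## Problem sizes used in the tests

The shipped test-and-acceptance suite runs at desk scale: interaction
recovery uses 200 replicate cohorts at the study's size (n = 251 women),
null screen calibration 200 cohorts of 360 subjects by 95 SNPs, the joint
discovery property 20 cohorts through all three differential-abundance
routes, and large-sample checks use single cohorts of 10,000-100,000
subjects. These sizes put Monte-Carlo standard errors well below the
asserted tolerances while keeping the whole suite in the minutes range.

## Known limitations

The LEfSe-style score is a faithful two-class core, not a re-implementation
of the Galaxy tool (no subclass stage, simplified bootstrap); the ZIG model
omits the moderated-variance refinements of the metagenomeSeq
implementation; CSS's `"auto"` quantile implements the published stability
idea rather than byte-matching any particular release. The selection
pipeline inherits the method's own winner's-curse bias described above -
a property of the procedure, reproduced deliberately.
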