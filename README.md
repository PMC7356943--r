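# microgrs

Gene-microbiome interaction analysis for adiposity with data-driven genetic
risk scores.

## What this is for

Host genetics and the gut microbiome both shape body-mass index (BMI), and
their interplay - does a taxon's effect on adiposity depend on the host's
genetic burden, and does the answer differ by sex? - is the question this
package operationalizes. It is aimed at nutrigenetics / microbiome
researchers who have, per subject: genotypes at a panel of obesity-related
SNPs, a family-level 16S count table, and anthropometric covariates.

The pipeline has three scientific layers:

1. **A data-driven genetic risk score (GRS).** For each SNP, Kruskal-Wallis
   tests screen the three genotype groups against BMI (p < 0.20); pairwise
   Mann-Whitney post-hocs merge genotypes with similar effects and label the
   higher-BMI side the *risk* category; a confirmatory Mann-Whitney
   (p < 0.10) plus low-count (<10%) and collinearity (|r| > 0.8) filters
   select the final loci. The score counts loci at which a subject carries
   the risk genotype: GRS = sum over retained loci of 1{genotype in risk
   category}, so a subject with risk genotypes at 6 of 10 loci scores 6.
2. **Family-level microbiome statistics.** Cumulative sum scaling (CSS)
   normalization; Shannon (nats), bias-corrected Chao1 and Bray-Curtis
   diversity; and three differential-abundance routes between two groups
   (WHO BMI classes, or low/high GRS at the mean split): an LEfSe-style
   Kruskal-Wallis + bootstrapped LDA effect size (log10 scale, threshold
   2.0), a zero-inflated Gaussian (ZIG) EM regression on log2 CSS counts
   with Benjamini-Hochberg FDR, and a random-forest mean-decrease-accuracy
   (MDA) ranking validated by holdout ROC AUC.
3. **Interaction regressions.** `BMI ~ family + GRS + family:GRS + age +
   METs + energy (+ sex)`, pooled and sex-stratified, with predicted-BMI
   curves over the GRS range at 5% and 15% family abundance.

Because subject-level data for this design are typically not public, the
package includes a first-class synthetic cohort generator (95 HWE SNPs with
ten planted mixed-dominance effects, a 64-family zero-inflated log-normal
count matrix, and a female-specific Prevotellaceae-by-GRS interaction on
BMI) against which every stage is tested. See the methods vignette
(`vignettes/gene-microbiome-adiposity.Rmd`) for models, assumptions and
parameter choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run it
from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_build_grs.R
Rscript analysis/03_diversity.R
Rscript analysis/04_differential_abundance.R
Rscript analysis/05_interaction_models.R
```

Step 1 generates the default synthetic cohort and prints its marginals:

```
cohort: 360 subjects, 252 women / 108 men
BMI mean 30.0 (SD 6.7); classes: normalweight 23 %, overweight 35 %, obese 42 %
planted GRS mean 6.03; focal family mean abundance 8.8%
```

Step 2 runs the three-stage selection (24 of 95 SNPs pass the screen; 20
survive confirmation, including 8 of the 10 planted loci - the data-driven
funnel also admits some null loci, which is a property of the method) and
shows the constructed score separating the WHO groups: mean GRS 9.66 in
normal weight vs 12.11 in overweight+obese.

Step 4 triangulates the planted focal family across all three
differential-abundance routes, e.g. for the BMI split:

```
LEfSe-style biomarkers (LDA >= 2): Ruminococcaceae (4.47, normalweight); Prevotellaceae (4.4, overweight+obese); ...
ZIG q < 0.05: Prevotellaceae (log2FC 0.73, q 5.4e-08)
random forest: top family Prevotellaceae (mean MDA 0.0187), holdout AUC 0.66
```

Prevotellaceae is the only family significant under ZIG and ranks first in
MDA for both the BMI and the GRS split. Step 5 fits the interaction models
against the *constructed* GRS:

```
all    n = 360  interaction beta =  0.023 +/- 0.015  p = 0.128  adjR2 = 0.65
men    n = 108  interaction beta = -0.014 +/- 0.019  p = 0.479  adjR2 = 0.31
women  n = 252  interaction beta =  0.035 +/- 0.018  p = 0.047  adjR2 = 0.73
```

The sex-specific pattern planted in the generator comes through: a positive,
significant interaction in women, none in men - higher focal-family
abundance steepens the BMI-vs-GRS slope only in the female stratum (the
predicted-curve table quantifies the widening gap). The coefficient is
attenuated relative to the planted 0.10 because the constructed score is a
noisy version of the true genetic burden; fitting against the planted score
recovers 0.10, which is what the acceptance checks assert.

In code, the core calls are:

```r
library(microgrs)
sim <- simulate_cohort(cohort_config(seed = 1))
g   <- build_grs(sim$genotypes, sim$cohort$bmi, sex = sim$cohort$sex)
fit <- interaction_model(sim$cohort$bmi, sim$cohort$focal_relabund,
                         sim$cohort$true_grs,
                         sim$cohort[, c("sex", "age", "mets", "energy")],
                         stratum = "women")
predict_curve(fit, family_values = c(5, 15), grs_range = 0:10)
```

`run_pipeline(run_config(outdir = "run1", seed = 1))` executes all stages in
one call and writes the report tables plus a JSON manifest that reproduces
the run.

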