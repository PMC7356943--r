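# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: 95
# biallelic SNPs in Hardy-Weinberg equilibrium (10 truly BMI-associated under
# mixed dominance patterns), a 64-family zero-inflated log-normal count
# matrix with variable library size, covariates matching a mixed-weight
# adult cohort, and a female-specific focal-family-by-GRS interaction on BMI.

.EFFECT_MODELS <- c("none", "additive", "dominant", "recessive",
                    "heterozygote-disadvantage")

#' Define a SNP for simulation
#'
#' @param snp_id label.
#' @param alleles length-2 character vector, major allele first.
#' @param maf minor-allele frequency in `[0, 0.5]`.
#' @param effect_model one of `"none"`, `"additive"`, `"dominant"`,
#'   `"recessive"`, `"heterozygote-disadvantage"`. Models are expressed
#'   relative to the minor allele; `"heterozygote-disadvantage"` puts the
#'   effect on the heterozygote. A negative `effect_size` flips which side of
#'   the partition carries the higher BMI, so e.g. a negative
#'   heterozygote-disadvantage effect yields the "both homozygotes are the
#'   risk group" coding shape.
#' @param effect_size BMI shift (kg/m2) of the effect-carrying genotype
#'   category; must be 0 exactly when `effect_model` is `"none"`.
#' @return one-row data frame; rows from several calls can be `rbind`-ed into
#'   a spec table.
#' @export
snp_spec <- function(snp_id, alleles, maf, effect_model = "none",
                     effect_size = 0) {
  stopifnot(length(alleles) == 2, is.character(alleles))
  if (!is.numeric(maf) || is.na(maf) || maf < 0 || maf > 0.5) {
    stop("maf must lie in [0, 0.5] (got ", maf, ")")
  }
  effect_model <- match.arg(effect_model, .EFFECT_MODELS)
  if ((effect_model == "none") != (effect_size == 0)) {
    stop("effect_size must be 0 exactly when effect_model is 'none'")
  }
  data.frame(snp_id = snp_id, allele1 = alleles[1], allele2 = alleles[2],
             maf = maf, effect_model = effect_model,
             effect_size = effect_size, stringsAsFactors = FALSE)
}

#' Default 95-SNP panel
#'
#' Ninety-five biallelic loci: ten BMI-associated obesity-gene SNPs with
#' mixed dominance patterns (dominant, recessive and heterozygote codings,
#' effect magnitudes of 1.3-1.6 kg/m2, matching the 1-2 kg/m2 genotype-group
#' contrasts typical of single obesity loci) and 85 null loci with minor
#' allele frequencies spread over 0.05-0.5.
#'
#' @return spec table (one row per SNP) accepted by [simulate_genotypes()].
#' @export
default_snp_specs <- function() {
  planted <- rbind(
    snp_spec("rs4731426_LEP",     c("G", "C"), 0.45, "heterozygote-disadvantage", -1.4),
    snp_spec("rs1800006_UCP3",    c("G", "A"), 0.30, "heterozygote-disadvantage", -1.5),
    snp_spec("rs1052700_PLIN1",   c("T", "A"), 0.45, "dominant",                   1.6),
    snp_spec("rs1042713_ADRB2",   c("G", "A"), 0.40, "dominant",                  -1.5),
    snp_spec("rs11605924_CRY2",   c("C", "A"), 0.45, "dominant",                   1.4),
    snp_spec("rs1800592_UCP1",    c("C", "T"), 0.25, "heterozygote-disadvantage",  1.3),
    snp_spec("rs2734827_UCP3",    c("G", "A"), 0.30, "dominant",                   1.4),
    snp_spec("rs1440581_PPM1K",   c("T", "C"), 0.45, "recessive",                 -1.4),
    snp_spec("rs7799039_LEP",     c("G", "A"), 0.45, "heterozygote-disadvantage", -1.3),
    snp_spec("rs12255372_TCF7L2", c("G", "T"), 0.30, "recessive",                 -1.5)
  )
  n_null <- 85L
  mafs <- round(seq(0.05, 0.5, length.out = n_null), 4)
  nulls <- do.call(rbind, lapply(seq_len(n_null), function(i) {
    snp_spec(sprintf("rs_null%02d", i), c("A", "G"), mafs[i], "none", 0)
  }))
  rbind(planted, nulls)
}

# Genotype category strings for one spec row: hom-major, het, hom-minor.
.genotype_categories <- function(a1, a2) {
  c(paste0(a1, a1), paste0(a1, a2), paste0(a2, a2))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP column is drawn i.i.d. with genotype probabilities
#' `(1-p)^2, 2p(1-p), p^2` for `p = maf`; loci are independent (no linkage
#' disequilibrium).
#'
#' @param specs spec table from [snp_spec()] / [default_snp_specs()].
#' @param n number of subjects.
#' @param seed integer seed; identical specs + seed give identical matrices.
#' @return character matrix of genotype strings, subjects x SNPs, with
#'   subject ids as rownames and SNP ids as colnames.
#' @export
simulate_genotypes <- function(specs, n, seed = 1) {
  stopifnot(n >= 1)
  if (any(specs$maf < 0 | specs$maf > 0.5)) {
    stop("all minor-allele frequencies must lie in [0, 0.5]")
  }
  set.seed(seed)
  g <- matrix(NA_character_, nrow = n, ncol = nrow(specs),
              dimnames = list(sprintf("S%04d", seq_len(n)), specs$snp_id))
  for (j in seq_len(nrow(specs))) {
    p <- specs$maf[j]
    cats <- .genotype_categories(specs$allele1[j], specs$allele2[j])
    g[, j] <- sample(cats, n, replace = TRUE,
                     prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  g
}

#' Cohort-level simulation settings
#'
#' Defaults mirror the reference cohort: 360 subjects, 70% women (251/360),
#' age 44.8 (SD 10) years, physical activity 25.3 (SD 15) METs, energy intake
#' 2907 (SD 900) kcal, and a BMI model whose baseline is set so the simulated
#' population lands near the 18/30/52% normal-weight/overweight/obese split
#' with mean BMI close to 29.9 kg/m2. The female-stratum
#' focal-family-by-GRS interaction defaults to 0.10 kg/m2 per
#' (percent abundance x GRS unit); the male stratum defaults to 0.
#'
#' @param n_subjects cohort size.
#' @param female_fraction probability a subject is female.
#' @param age_mean,age_sd,mets_mean,mets_sd,energy_mean,energy_sd covariate
#'   normal distributions, truncated at plausibility bounds (age >= 18,
#'   METs >= 0, energy >= 500 kcal).
#' @param bmi_baseline intercept of the BMI model (kg/m2).
#' @param bmi_noise_sd residual BMI standard deviation (kg/m2).
#' @param interaction_beta_female,interaction_beta_male interaction effect,
#'   kg/m2 per (percent relative abundance x GRS unit).
#' @param seed integer seed.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 360L, female_fraction = 251 / 360,
                          age_mean = 44.8, age_sd = 10,
                          mets_mean = 25.3, mets_sd = 15,
                          energy_mean = 2907, energy_sd = 900,
                          bmi_baseline = 25.9, bmi_noise_sd = 3,
                          interaction_beta_female = 0.10,
                          interaction_beta_male = 0,
                          seed = 1L) {
  stopifnot(n_subjects >= 1,
            female_fraction >= 0, female_fraction <= 1,
            age_sd >= 0, mets_sd >= 0, energy_sd >= 0, bmi_noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 mets_mean = mets_mean, mets_sd = mets_sd,
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 bmi_baseline = bmi_baseline, bmi_noise_sd = bmi_noise_sd,
                 interaction_beta_female = interaction_beta_female,
                 interaction_beta_male = interaction_beta_male,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate subject covariates
#'
#' Sex is Bernoulli(`female_fraction`); age, METs and energy are normal draws
#' truncated (by clipping) at 18 years, 0 METs and 500 kcal respectively.
#'
#' @param config a [cohort_config()].
#' @param n number of subjects (defaults to `config$n_subjects`).
#' @return data frame with `subject_id`, `sex`, `age`, `mets`, `energy`.
#' @export
simulate_covariates <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  sex <- factor(ifelse(stats::runif(n) < config$female_fraction,
                       "female", "male"),
                levels = c("female", "male"))
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age = pmax(18, stats::rnorm(n, config$age_mean, config$age_sd)),
    mets = pmax(0, stats::rnorm(n, config$mets_mean, config$mets_sd)),
    energy = pmax(500, stats::rnorm(n, config$energy_mean, config$energy_sd)),
    stringsAsFactors = FALSE
  )
}

#' Microbiome simulation settings
#'
#' A 64-family zero-inflated log-normal count model. Per-family log-means
#' follow a power-law rank-abundance curve (`rank^-1.1`), log-SDs are 1, and
#' zero-inflation rises linearly from 0 to 0.7 with rarity. The focal family
#' ("Prevotellaceae", rank 3, mean relative abundance around 7%) can be
#' shifted between high- and low-genetic-risk subjects by
#' `focal_shift_log2` log2 units (default 1, a twofold contrast spanning the
#' abundance range at which the interaction models are evaluated). Library
#' sizes are negative binomial with the given mean and dispersion, floored
#' at 1000 reads.
#'
#' @param n_families number of families.
#' @param log_mean,log_sd,zero_inflation per-family vectors (recycled).
#' @param libsize_mean,libsize_dispersion library-size negative binomial
#'   parameters (`size = 1/dispersion`).
#' @param focal_family label of the focal family; must be present.
#' @param focal_shift_log2 planted log2 abundance shift of the focal family
#'   in the high-genetic-risk group.
#' @return validated config list of class `microbiome_config`.
#' @export
microbiome_config <- function(n_families = 64L,
                              log_mean = NULL, log_sd = NULL,
                              zero_inflation = NULL,
                              libsize_mean = 5e4, libsize_dispersion = 0.2,
                              focal_family = "Prevotellaceae",
                              focal_shift_log2 = 1) {
  stopifnot(n_families >= 1)
  named <- c("Ruminococcaceae", "Lachnospiraceae", "Prevotellaceae",
             "Bacteroidaceae", "Veillonellaceae", "Rikenellaceae",
             "Porphyromonadaceae", "Christensenellaceae", "Lactobacillaceae",
             "Peptostreptococcaceae", "Leuconostocaceae", "Catabacteriaceae")
  labels <- c(named, sprintf("Family_%02d", seq_len(max(0, n_families - length(named)))))
  labels <- labels[seq_len(n_families)]
  i <- seq_len(n_families)
  if (is.null(log_mean)) log_mean <- log(i^-1.1)
  if (is.null(log_sd)) {
    # prevalent dominant families fluctuate less on the log scale; this also
    # keeps the focal family's abundance spread inside the 5-15% window the
    # interaction models are evaluated at
    log_sd <- rep(1, n_families)
    log_sd[match(focal_family, labels)] <- 0.5
  }
  if (is.null(zero_inflation)) zero_inflation <- 0.7 * (i - 1) / max(1, n_families - 1)
  log_mean <- rep_len(log_mean, n_families)
  log_sd <- rep_len(log_sd, n_families)
  zero_inflation <- rep_len(zero_inflation, n_families)
  if (any(zero_inflation < 0 | zero_inflation >= 1)) {
    stop("zero_inflation must lie in [0, 1)")
  }
  if (!focal_family %in% labels) {
    stop("focal_family '", focal_family, "' is not among the family labels")
  }
  structure(list(n_families = as.integer(n_families), families = labels,
                 log_mean = log_mean, log_sd = log_sd,
                 zero_inflation = zero_inflation,
                 libsize_mean = libsize_mean,
                 libsize_dispersion = libsize_dispersion,
                 focal_family = focal_family,
                 focal_shift_log2 = focal_shift_log2),
            class = "microbiome_config")
}

#' Simulate a family-level count matrix
#'
#' Per cell, the latent intensity is zero with the family's zero-inflation
#' probability and log-normal otherwise; intensities are normalized within a
#' sample and scaled to a negative-binomial library size, then rounded to
#' integer counts. When `focal_group` is supplied, the focal family's
#' log-mean is raised by `focal_shift_log2 * log(2)` for subjects with
#' `focal_group == 1` (the planted high-genetic-risk signal).
#'
#' @param config a [microbiome_config()].
#' @param n number of samples.
#' @param seed integer seed.
#' @param focal_group optional 0/1 vector of length `n`.
#' @return integer count matrix, families x samples.
#' @export
simulate_microbiome <- function(config, n, seed = 1, focal_group = NULL) {
  stopifnot(inherits(config, "microbiome_config"), n >= 1)
  if (!is.null(focal_group)) stopifnot(length(focal_group) == n)
  set.seed(seed)
  k <- config$n_families
  mu <- matrix(config$log_mean, nrow = k, ncol = n)
  if (!is.null(focal_group)) {
    fi <- match(config$focal_family, config$families)
    mu[fi, ] <- mu[fi, ] + config$focal_shift_log2 * log(2) * focal_group
  }
  present <- matrix(stats::runif(k * n), k, n) >=
    matrix(config$zero_inflation, k, n)
  w <- present * exp(mu + matrix(config$log_sd, k, n) *
                       matrix(stats::rnorm(k * n), k, n))
  # guard: a sample where every family dropped out keeps its most abundant one
  dead <- colSums(w) == 0
  if (any(dead)) {
    top <- which.max(config$log_mean)
    w[top, dead] <- exp(config$log_mean[top])
  }
  lib <- pmax(1000, stats::rnbinom(n, mu = config$libsize_mean,
                                   size = 1 / config$libsize_dispersion))
  props <- sweep(w, 2, colSums(w), "/")
  counts <- round(sweep(props, 2, lib, "*"))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(config$families, sprintf("S%04d", seq_len(n)))
  counts
}

# Per-subject effect-category indicator for one spec row (0/1; additive gives
# the half-dosage 0, 0.5, 1).
.effect_indicator <- function(genotype, spec_row) {
  cats <- .genotype_categories(spec_row$allele1, spec_row$allele2)
  dosage <- match(.canonical_genotype(genotype),
                  .canonical_genotype(cats)) - 1L
  if (anyNA(dosage)) stop("genotype not among the categories of ",
                          spec_row$snp_id)
  switch(spec_row$effect_model,
         "none" = rep(0, length(genotype)),
         "additive" = dosage / 2,
         "dominant" = as.numeric(dosage >= 1),
         "recessive" = as.numeric(dosage == 2),
         "heterozygote-disadvantage" = as.numeric(dosage == 1))
}

# Risk indicator (category associated with HIGHER BMI) for one spec row.
.risk_indicator <- function(genotype, spec_row) {
  d <- .effect_indicator(genotype, spec_row)
  if (spec_row$effect_model == "additive") d <- as.numeric(d > 0)
  if (spec_row$effect_size < 0) d <- 1 - d
  d
}

#' Simulate BMI from genotypes, covariates and focal-family abundance
#'
#' `BMI = baseline + sum(effect_k * indicator_k) + beta_sex *
#' (focal_relabund * true_grs) + N(0, noise_sd)`, where `true_grs` is the
#' planted per-locus risk-indicator sum over the BMI-associated loci and
#' `beta_sex` is the sex-specific interaction coefficient.
#'
#' @param genotypes matrix from [simulate_genotypes()].
#' @param covariates data frame from [simulate_covariates()] (uses `sex`).
#' @param focal_relabund focal-family relative abundance per subject, percent.
#' @param specs the spec table used to simulate `genotypes`.
#' @param config a [cohort_config()].
#' @return data frame with `bmi` and `true_grs`.
#' @export
simulate_bmi <- function(genotypes, covariates, focal_relabund, specs,
                         config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(genotypes)
  if (nrow(covariates) != n || length(focal_relabund) != n) {
    stop("genotypes, covariates and focal_relabund must describe the same subjects")
  }
  set.seed(config$seed + 2L)
  planted <- specs[specs$effect_model != "none", , drop = FALSE]
  genetic <- rep(0, n)
  true_grs <- rep(0L, n)
  for (j in seq_len(nrow(planted))) {
    row <- planted[j, ]
    genetic <- genetic + row$effect_size * .effect_indicator(genotypes[, row$snp_id], row)
    true_grs <- true_grs + as.integer(.risk_indicator(genotypes[, row$snp_id], row))
  }
  beta <- ifelse(covariates$sex == "female",
                 config$interaction_beta_female,
                 config$interaction_beta_male)
  bmi <- config$bmi_baseline + genetic +
    beta * focal_relabund * true_grs +
    stats::rnorm(n, 0, config$bmi_noise_sd)
  bmi <- pmax(bmi, 1)  # positivity guard; essentially never binds at defaults
  data.frame(bmi = bmi, true_grs = true_grs)
}

#' Simulate a complete cohort
#'
#' Runs genotypes -> covariates -> planted GRS -> microbiome (focal family
#' shifted in the high-genetic-risk half) -> BMI, all from one seed.
#'
#' @param config a [cohort_config()].
#' @param specs SNP spec table.
#' @param mb_config a [microbiome_config()].
#' @return list with `cohort` (subject table including `bmi` and `true_grs`),
#'   `genotypes`, `counts`, and the three configuration objects.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            specs = default_snp_specs(),
                            mb_config = microbiome_config()) {
  n <- config$n_subjects
  genotypes <- simulate_genotypes(specs, n, seed = config$seed)
  covariates <- simulate_covariates(config)
  planted <- specs[specs$effect_model != "none", , drop = FALSE]
  true_grs <- rep(0L, n)
  for (j in seq_len(nrow(planted))) {
    row <- planted[j, ]
    true_grs <- true_grs + as.integer(.risk_indicator(genotypes[, row$snp_id], row))
  }
  focal_group <- as.numeric(true_grs >= mean(true_grs))
  counts <- simulate_microbiome(mb_config, n, seed = config$seed + 3L,
                                focal_group = focal_group)
  relab <- relative_abundance(counts)
  focal <- relab[mb_config$focal_family, ]
  bmi <- simulate_bmi(genotypes, covariates, focal, specs, config)
  cohort <- cbind(covariates,
                  focal_relabund = as.numeric(focal),
                  bmi = bmi$bmi, true_grs = bmi$true_grs)
  list(cohort = cohort, genotypes = genotypes, counts = counts,
       config = config, specs = specs, mb_config = mb_config)
}

#' Friedewald LDL cholesterol
#'
#' `LDL-c = TC - HDL-c - TG/5`, all in mg/dL. The formula is unreliable at
#' high triglycerides; values above 400 mg/dL trigger a warning.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol, triglycerides (mg/dL).
#' @return LDL cholesterol (mg/dL), vectorized.
#' @examples
#' friedewald_ldl(191, 64, 68)  # 113.4
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative")
  }
  if (any(tg > 400, na.rm = TRUE)) {
    warning("Friedewald formula is unreliable for triglycerides > 400 mg/dL")
  }
  tc - hdl - tg / 5
}
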