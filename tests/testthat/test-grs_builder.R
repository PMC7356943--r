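# Three-stage GRS construction: screening, risk coding, confirmation
# filters, scoring semantics, and the mean split.

test_that("HWE chi-square matches hand-computed expectations", {
  expect_equal(hwe_test(c(25, 50, 25))$statistic, 0)
  # maximal disequilibrium at allele frequency 0.5: statistic equals n
  expect_equal(hwe_test(c(50, 0, 50))$statistic, 100)
  # monomorphic locus fits perfectly
  expect_equal(hwe_test(c(77, 0, 0))$statistic, 0)
  expect_error(hwe_test(c(0, 0, 0)), "undefined")
})

test_that("the stage-1 screen flags passers and untestable SNPs", {
  set.seed(31)
  n <- 120
  g <- cbind(assoc = sample(c("AA", "AG", "GG"), n, TRUE, c(.36, .48, .16)),
             null = sample(c("CC", "CT", "TT"), n, TRUE, c(.49, .42, .09)),
             rare = c("AA", "AG", "AG", rep("AA", n - 3)),
             missing = rep(NA_character_, n))
  rownames(g) <- sprintf("S%03d", 1:n)
  bmi <- rnorm(n, 28, 3) + 6 * (g[, "assoc"] == "GG")
  res <- kw_screen(g, bmi)
  expect_equal(res$snp_id, colnames(g))
  expect_true(res$pass[res$snp_id == "assoc"])
  expect_true(res$untestable[res$snp_id == "missing"])
  expect_false(res$untestable[res$snp_id == "rare"])  # 2 groups with >= 2
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
})

test_that("risk codings merge similar genotypes and label the high side", {
  set.seed(8)
  # two high-median genotypes indistinguishable from each other but far from
  # the low one: they merge into the risk category
  g <- rep(c("GC", "GG", "CC"), each = 30)
  bmi <- c(rnorm(30, 26, 1), rnorm(30, 31, 1), rnorm(30, 31.2, 1))
  cod <- derive_risk_coding(g, bmi, snp_id = "snp")
  expect_false(cod$excluded)
  expect_setequal(cod$risk, c("GG", "CC"))
  expect_identical(cod$nonrisk, "GC")

  # heterozygote-advantage shape: het lowest, homozygotes merge as risk
  g2 <- rep(c("AG", "GG", "AA"), each = 25)
  bmi2 <- c(rnorm(25, 27, 1), rnorm(25, 30.5, 1), rnorm(25, 30.4, 1))
  cod2 <- derive_risk_coding(g2, bmi2)
  expect_setequal(cod2$risk, c("GG", "AA"))
  expect_identical(cod2$nonrisk, "AG")

  # indistinguishable groups cannot be coded
  cod3 <- derive_risk_coding(rep(c("AA", "AG", "GG"), 10), rep(27, 30))
  expect_true(cod3$excluded)

  # risk side always has the (weakly) higher median in training data
  for (seed in 1:20) {
    set.seed(seed)
    g4 <- sample(c("AA", "AG", "GG"), 60, TRUE)
    bmi4 <- rnorm(60, 29, 4)
    cod4 <- derive_risk_coding(g4, bmi4)
    if (!cod4$excluded) {
      expect_gte(median(bmi4[g4 %in% cod4$risk]),
                 median(bmi4[g4 %in% cod4$nonrisk]))
    }
  }
})

test_that("stage-3 filters exclude low-count and collinear codings", {
  set.seed(12)
  n <- 200
  # SNP A: strong signal, balanced categories. SNP B: identical indicator
  # (perfect collinearity). SNP C: risk category holds 5% of subjects.
  gA <- sample(c("AA", "GG"), n, TRUE)
  gB <- ifelse(gA == "AA", "CC", "TT")
  gC <- c(rep("TT", n * 0.05), rep("CC", n * 0.95))
  bmi <- rnorm(n, 28, 2) + 2 * (gA == "GG") + 2 * (gC == "TT")
  genotypes <- cbind(A = gA, B = gB, C = gC)
  rownames(genotypes) <- sprintf("S%03d", 1:n)
  codings <- lapply(colnames(genotypes), function(s) {
    derive_risk_coding(genotypes[, s], bmi, snp_id = s)
  })
  rep <- confirm_and_filter(codings, genotypes, bmi)
  expect_identical(rep$reason[rep$snp_id == "C"], "low-count")
  expect_equal(sum(rep$retained[rep$snp_id %in% c("A", "B")]), 1)
  expect_identical(rep$reason[rep$snp_id %in% c("A", "B") & !rep$retained],
                   "collinearity")
  expect_warning(confirm_and_filter(list(), genotypes, bmi), "empty")
})

test_that("GRS scoring is a per-locus indicator sum with strict bounds", {
  codings <- example_risk_codings()
  # helper: pick one genotype from the risk or non-risk category of a row
  pick <- function(row, risk, prefer_hom = TRUE) {
    cats <- strsplit(if (risk) row$risk_genotypes else row$nonrisk_genotypes,
                     "+", fixed = TRUE)[[1]]
    hom <- cats[substr(cats, 1, 1) == substr(cats, 2, 2)]
    if (prefer_hom && length(hom) > 0) hom[1] else cats[1]
  }
  g6 <- t(vapply(seq_len(10), function(i) {
    pick(codings[i, ], risk = i <= 6)
  }, character(1)))
  rownames(g6) <- "subj6"
  colnames(g6) <- codings$snp_id
  expect_equal(unname(compute_grs(codings, g6)), 6L)

  gall <- g6
  gall[1, ] <- vapply(seq_len(10), function(i) pick(codings[i, ], TRUE),
                      character(1))
  expect_equal(unname(compute_grs(codings, gall)), 10L)

  gnone <- g6
  gnone[1, ] <- vapply(seq_len(10), function(i) pick(codings[i, ], FALSE),
                       character(1))
  expect_equal(unname(compute_grs(codings, gnone)), 0L)

  # genotype order within the string is irrelevant ("TA" == "AT")
  gflip <- gall
  gflip[1, ] <- vapply(strsplit(gall[1, ], ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
  expect_equal(unname(compute_grs(codings, gflip)), 10L)

  # unknown category errors with SNP and subject named
  gbad <- gall
  gbad[1, 1] <- "XX"
  expect_error(compute_grs(codings, gbad), "rs4731426_LEP.*subj6")

  # missing genotype at a retained locus excludes the subject
  gmiss <- rbind(gall, gall)
  rownames(gmiss) <- c("ok", "dropme")
  gmiss["dropme", 3] <- NA
  sc <- compute_grs(codings, gmiss)
  expect_true(is.na(sc["dropme"]))
  expect_identical(attr(sc, "excluded_subjects"), "dropme")

  # additivity: dropping one locus lowers each score by its indicator
  sc10 <- compute_grs(codings, gall)
  sc9 <- compute_grs(codings[-1, ], gall)
  expect_equal(unname(sc10 - sc9), 1L)
})

test_that("the mean split sends ties upward and is shift invariant", {
  expect_identical(as.character(split_by_mean(c(5, 6, 7))),
                   c("low", "high", "high"))
  expect_identical(as.character(split_by_mean(c(0, 10))), c("low", "high"))
  set.seed(2)
  s <- rpois(50, 6)
  s[1] <- s[1] + 1L  # guarantee non-constant
  expect_identical(split_by_mean(s), split_by_mean(s + 3L))
  expect_warning(split_by_mean(rep(4, 5)), "constant")
})

test_that("the retained SNP set is invariant to subject and SNP order", {
  sim <- simulate_cohort(cohort_config(n_subjects = 150, seed = 13),
                         default_snp_specs()[c(1:10, 11:30), ])
  base <- build_grs(sim$genotypes, sim$cohort$bmi)
  set.seed(14)
  subj <- sample(nrow(sim$genotypes))
  snps <- sample(ncol(sim$genotypes))
  perm <- build_grs(sim$genotypes[subj, snps], sim$cohort$bmi[subj])
  expect_setequal(base$report$snp_id[base$report$retained],
                  perm$report$snp_id[perm$report$retained])
  expect_equal(base$grs[rownames(sim$genotypes)[subj]], perm$grs)
})
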