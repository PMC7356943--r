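# Data-driven genetic risk score construction.
#
# Three stages: (1) Kruskal-Wallis screen of each SNP's genotype groups
# against BMI at p < 0.20; (2) post-hoc pairwise Mann-Whitney tests to merge
# genotypes with similar effects and label the higher-BMI side "risk";
# (3) confirmatory two-group Mann-Whitney at p < 0.10 with low-count (<10%
# in either category) and collinearity (|r| > 0.8) exclusions. The GRS is
# the per-locus risk-indicator sum.

# Order-insensitive genotype string ("GA" == "AG").
.canonical_genotype <- function(g) {
  out <- vapply(strsplit(g, ""), function(ch) paste(sort(ch), collapse = ""),
                character(1))
  out[is.na(g)] <- NA_character_
  out
}

.collapse_genotypes <- function(gs) paste(gs, collapse = "+")
.split_genotypes <- function(s) strsplit(s, "+", fixed = TRUE)[[1]]

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against Hardy-Weinberg expectations at the sample allele frequency.
#'
#' @param counts length-3 vector of genotype counts: hom-major, het,
#'   hom-minor.
#' @return list with `statistic`, `df`, `p.value`, `allele_freq` (minor).
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: statistic 0
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("hwe_test() is undefined for all-zero genotype counts")
  p <- (2 * counts[3] + counts[2]) / (2 * n)  # minor-allele frequency
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- expected > 0
  stat <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       allele_freq = p)
}

#' Stage 1: Kruskal-Wallis screen of SNPs against BMI
#'
#' Tests every SNP's genotype groups (absence of the allele, one copy, two
#' copies) against BMI with the tie-corrected Kruskal-Wallis test and flags
#' SNPs with p below `alpha1` as stage-1 passers. SNPs without at least two
#' genotype groups of two or more subjects are flagged untestable.
#'
#' @param genotypes subjects x SNPs character matrix; `NA` = missing.
#' @param bmi numeric BMI vector aligned with the rows of `genotypes`.
#' @param alpha1 screening threshold (default 0.20).
#' @return data frame with one row per SNP: `snp_id`, `n`, `n_groups`,
#'   `statistic`, `p`, `pass`, `untestable`.
#' @export
kw_screen <- function(genotypes, bmi, alpha1 = 0.20) {
  stopifnot(nrow(genotypes) == length(bmi), alpha1 > 0, alpha1 <= 1)
  res <- lapply(colnames(genotypes), function(snp) {
    g <- genotypes[, snp]
    keep <- !is.na(g) & !is.na(bmi)
    g <- g[keep]
    b <- bmi[keep]
    sizes <- table(g)
    if (sum(sizes >= 2) < 2) {
      return(data.frame(snp_id = snp, n = length(b),
                        n_groups = length(sizes), statistic = NA_real_,
                        p = NA_real_, pass = FALSE, untestable = TRUE))
    }
    kt <- kw_test(b, g)
    data.frame(snp_id = snp, n = length(b), n_groups = length(sizes),
               statistic = kt$statistic, p = kt$p.value,
               pass = kt$p.value < alpha1, untestable = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stage 2: derive the risk/non-risk genotype coding for one SNP
#'
#' Genotype groups are ordered by median BMI; adjacent groups whose pairwise
#' Mann-Whitney p is at least `merge_alpha` are merged ("genotypes with
#' similar effects clustered in a single category"). When the merging rule
#' does not single out one cut (all three groups distinct, or all pairs
#' similar), the median-ordered binary split with the stronger two-group
#' Mann-Whitney separation is chosen. The side with the higher median BMI is
#' labelled risk. SNPs whose groups are indistinguishable (best split p = 1)
#' are flagged for exclusion.
#'
#' @param genotypes genotype strings for one SNP (`NA` = missing).
#' @param bmi aligned BMI vector.
#' @param merge_alpha post-hoc merge threshold (default 0.05).
#' @param snp_id optional label carried into the result.
#' @return list of class `risk_coding` with `snp_id`, `risk`, `nonrisk`
#'   (character vectors of genotype categories), `stage2_p` (the chosen
#'   split's Mann-Whitney p), `excluded`, `reason`.
#' @export
derive_risk_coding <- function(genotypes, bmi, merge_alpha = 0.05,
                               snp_id = NA_character_) {
  keep <- !is.na(genotypes) & !is.na(bmi)
  g <- genotypes[keep]
  b <- bmi[keep]
  coding <- function(risk, nonrisk, p, excluded = FALSE, reason = NA_character_) {
    structure(list(snp_id = snp_id, risk = risk, nonrisk = nonrisk,
                   stage2_p = p, excluded = excluded, reason = reason),
              class = "risk_coding")
  }
  groups <- unique(g)
  if (length(groups) < 2) {
    return(coding(character(0), groups, NA_real_, TRUE, "single-genotype"))
  }
  med <- vapply(groups, function(x) stats::median(b[g == x]), numeric(1))
  mn <- vapply(groups, function(x) mean(b[g == x]), numeric(1))
  ord <- order(med, mn, groups)  # ties broken by mean, then label
  groups <- groups[ord]
  k <- length(groups)
  split_p <- function(cut) {
    lab <- g %in% groups[(cut + 1):k]  # TRUE = upper (higher-median) side
    mw_test(b, lab)$p.value
  }
  cut <- if (k == 2) {
    1L
  } else {
    adj <- vapply(seq_len(k - 1), function(i) {
      sel <- g %in% groups[c(i, i + 1)]
      mw_test(b[sel], g[sel])$p.value
    }, numeric(1))
    similar <- adj >= merge_alpha
    if (sum(similar) == 1L) {
      which(!similar)  # merge across the one similar boundary, cut at the other
    } else {
      # all-distinct or all-similar: take the better-separating binary split
      ps <- vapply(seq_len(k - 1), split_p, numeric(1))
      which.min(ps)
    }
  }
  p <- split_p(cut)
  risk <- groups[(cut + 1):k]
  nonrisk <- groups[seq_len(cut)]
  # enforce the defining property: risk side has the (weakly) higher median
  if (stats::median(b[g %in% risk]) < stats::median(b[g %in% nonrisk])) {
    tmp <- risk; risk <- nonrisk; nonrisk <- tmp
  }
  if (p >= 1 - 1e-12) {
    return(coding(risk, nonrisk, p, TRUE, "no-separation"))
  }
  coding(risk, nonrisk, p)
}

#' Stage 3: confirm codings and build the selection report
#'
#' Applies the confirmatory two-group Mann-Whitney test to each stage-2
#' coding and excludes SNPs that are non-significant at `alpha2`, have fewer
#' than `min_frac` of genotyped subjects in either category, or are
#' collinear (pairwise Pearson |r| of the 0/1 risk indicators above
#' `collinearity_r`; the member with the larger stage-3 p is dropped).
#'
#' @param codings list of [derive_risk_coding()] results.
#' @param genotypes subjects x SNPs matrix.
#' @param bmi aligned BMI vector.
#' @param alpha2 confirmation threshold (default 0.10).
#' @param min_frac minimum fraction of genotyped subjects per category.
#' @param collinearity_r absolute Pearson correlation cutoff.
#' @param stage1 optional [kw_screen()] result; its p-values are carried into
#'   the report.
#' @param sex optional sex factor aligned with `bmi`; adds the sex-stratified
#'   group BMI means and Mann-Whitney p-values of the published report
#'   layout.
#' @return `selection_report` data frame: one row per candidate SNP with the
#'   coding, group sizes, test p-values, exclusion flag/reason and `retained`.
#' @export
confirm_and_filter <- function(codings, genotypes, bmi, alpha2 = 0.10,
                               min_frac = 0.10, collinearity_r = 0.8,
                               stage1 = NULL, sex = NULL) {
  if (length(codings) == 0) {
    warning("empty candidate set: no codings to confirm")
    out <- data.frame(snp_id = character(0))
    class(out) <- c("selection_report", class(out))
    return(out)
  }
  indicator <- function(cod) {
    g <- .canonical_genotype(genotypes[, cod$snp_id])
    ind <- rep(NA_real_, length(g))
    ind[g %in% .canonical_genotype(cod$risk)] <- 1
    ind[g %in% .canonical_genotype(cod$nonrisk)] <- 0
    ind
  }
  rows <- lapply(codings, function(cod) {
    row <- data.frame(
      snp_id = cod$snp_id,
      nonrisk_genotypes = .collapse_genotypes(cod$nonrisk),
      risk_genotypes = .collapse_genotypes(cod$risk),
      n_nonrisk = NA_integer_, n_risk = NA_integer_,
      stage1_p = NA_real_, stage3_p = NA_real_,
      excluded = cod$excluded,
      reason = cod$reason, stringsAsFactors = FALSE)
    if (!cod$excluded) {
      ind <- indicator(cod)
      ok <- !is.na(ind) & !is.na(bmi)
      row$n_nonrisk <- sum(ind[ok] == 0)
      row$n_risk <- sum(ind[ok] == 1)
      row$stage3_p <- mw_test(bmi[ok], ind[ok])$p.value
      if (min(row$n_risk, row$n_nonrisk) / sum(ok) < min_frac) {
        row$excluded <- TRUE
        row$reason <- "low-count"
      } else if (row$stage3_p >= alpha2) {
        row$excluded <- TRUE
        row$reason <- "nonsignificant"
      }
      if (!is.null(sex)) {
        for (s in levels(factor(sex))) {
          sel <- ok & sex == s
          row[[paste0("bmi_nonrisk_", s)]] <- mean(bmi[sel & ind == 0])
          row[[paste0("bmi_risk_", s)]] <- mean(bmi[sel & ind == 1])
          row[[paste0("p_", s)]] <-
            if (length(unique(ind[sel])) == 2) mw_test(bmi[sel], ind[sel])$p.value
            else NA_real_
        }
      }
    }
    row
  })
  report <- do.call(rbind, rows)
  if (!is.null(stage1)) {
    report$stage1_p <- stage1$p[match(report$snp_id, stage1$snp_id)]
  }
  # collinearity pruning among survivors
  alive <- which(!report$excluded)
  if (length(alive) > 1) {
    ind_mat <- vapply(codings[alive], indicator, numeric(nrow(genotypes)))
    repeat {
      live <- which(!report$excluded[alive])
      if (length(live) < 2) break
      r <- suppressWarnings(
        stats::cor(ind_mat[, live, drop = FALSE],
                   use = "pairwise.complete.obs"))
      diag(r) <- 0
      r[is.na(r)] <- 0
      if (max(abs(r)) <= collinearity_r) break
      worst <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
      pair <- alive[live[worst]]
      drop <- pair[which.max(report$stage3_p[pair])]  # ties: later SNP goes
      report$excluded[drop] <- TRUE
      report$reason[drop] <- "collinearity"
    }
  }
  report$retained <- !report$excluded
  rownames(report) <- NULL
  class(report) <- c("selection_report", class(report))
  report
}

#' Compute the genetic risk score
#'
#' One point per retained locus at which the subject's genotype falls in the
#' risk category (a per-locus binary indicator sum, not an allele count: a
#' subject with risk genotypes at 6 of 10 loci scores 6). Subjects missing a
#' genotype at any retained locus get `NA` and are listed in the
#' `excluded_subjects` attribute.
#'
#' @param codings a [confirm_and_filter()] report (its retained rows are
#'   used) or any data frame with `snp_id`, `risk_genotypes`,
#'   `nonrisk_genotypes` columns (genotype categories joined by "+").
#' @param genotypes subjects x SNPs character matrix.
#' @return named integer vector of scores in `0..K` (K = retained loci).
#' @export
compute_grs <- function(codings, genotypes) {
  if ("retained" %in% names(codings)) {
    codings <- codings[codings$retained, , drop = FALSE]
  }
  if (nrow(codings) == 0) stop("no retained SNPs: cannot compute a GRS")
  missing_snps <- setdiff(codings$snp_id, colnames(genotypes))
  if (length(missing_snps) > 0) {
    stop("genotypes lack retained SNP(s): ",
         paste(missing_snps, collapse = ", "))
  }
  n <- nrow(genotypes)
  score <- rep(0L, n)
  miss <- rep(FALSE, n)
  for (i in seq_len(nrow(codings))) {
    snp <- codings$snp_id[i]
    g <- .canonical_genotype(genotypes[, snp])
    risk <- .canonical_genotype(.split_genotypes(codings$risk_genotypes[i]))
    nonrisk <- .canonical_genotype(.split_genotypes(codings$nonrisk_genotypes[i]))
    unknown <- !is.na(g) & !(g %in% c(risk, nonrisk))
    if (any(unknown)) {
      bad <- which(unknown)[1]
      stop("unknown genotype category '", genotypes[bad, snp], "' at ", snp,
           " for subject ", rownames(genotypes)[bad])
    }
    miss <- miss | is.na(g)
    score <- score + as.integer(g %in% risk)
  }
  score[miss] <- NA_integer_
  names(score) <- rownames(genotypes)
  if (any(miss)) {
    attr(score, "excluded_subjects") <- rownames(genotypes)[miss]
  }
  score
}

#' Split subjects into high and low genetic-risk groups at the mean
#'
#' High risk means score greater than or equal to the population mean (ties
#' at the mean go to the high group).
#'
#' @param grs integer score vector from [compute_grs()]; `NA` propagates.
#' @return factor with levels `low`, `high`.
#' @export
split_by_mean <- function(grs) {
  scores <- grs[!is.na(grs)]
  if (length(scores) < 2) stop("split_by_mean() needs at least 2 subjects")
  if (length(unique(scores)) == 1) {
    warning("constant scores: every subject lands in the high group")
  }
  factor(ifelse(grs >= mean(scores), "high", "low"), levels = c("low", "high"))
}

#' Run the full three-stage GRS construction
#'
#' Convenience wrapper: screen, code, confirm, score.
#'
#' @inheritParams kw_screen
#' @inheritParams derive_risk_coding
#' @inheritParams confirm_and_filter
#' @return list with `stage1` (screen table), `report` (selection report) and
#'   `grs` (scores for all subjects).
#' @export
build_grs <- function(genotypes, bmi, sex = NULL, alpha1 = 0.20,
                      merge_alpha = 0.05, alpha2 = 0.10, min_frac = 0.10,
                      collinearity_r = 0.8) {
  stage1 <- kw_screen(genotypes, bmi, alpha1 = alpha1)
  passers <- stage1$snp_id[stage1$pass]
  codings <- lapply(passers, function(snp) {
    derive_risk_coding(genotypes[, snp], bmi, merge_alpha = merge_alpha,
                       snp_id = snp)
  })
  report <- confirm_and_filter(codings, genotypes, bmi, alpha2 = alpha2,
                               min_frac = min_frac,
                               collinearity_r = collinearity_r,
                               stage1 = stage1, sex = sex)
  grs <- if (any(report$retained)) compute_grs(report, genotypes) else NULL
  list(stage1 = stage1, report = report, grs = grs)
}
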