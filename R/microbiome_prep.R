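# Family-level count-matrix preparation and diversity.
#
# Matrices are families x samples with non-negative integer counts; library
# size is the column sum. Shannon (nats), Chao1 (bias-corrected) and
# Bray-Curtis delegate to vegan behind this module's surface.

.check_abundance <- function(m) {
  if (!is.matrix(m) || any(m < 0)) {
    stop("expected a families x samples matrix of non-negative counts")
  }
  invisible(m)
}

#' Filter rare families
#'
#' Keeps families present (count > 0) in at least `min_prevalence` of the
#' samples and with total count at least `min_total`. Removed families are
#' reported via `message()`.
#'
#' @param m families x samples count matrix.
#' @param min_prevalence minimum fraction of samples with a nonzero count.
#' @param min_total minimum total count across samples.
#' @return the filtered matrix.
#' @export
filter_features <- function(m, min_prevalence = 0.10, min_total = 10) {
  .check_abundance(m)
  prev <- rowMeans(m > 0)
  keep <- prev >= min_prevalence & rowSums(m) >= min_total
  if (!any(keep)) {
    stop("filtering removed every family (min_prevalence = ", min_prevalence,
         ", min_total = ", min_total, ")")
  }
  if (any(!keep)) {
    message("filter_features: removed ", sum(!keep), " of ", nrow(m),
            " families")
  }
  m[keep, , drop = FALSE]
}

#' Relative abundance on the percent scale
#'
#' Each sample (column) is rescaled to sum to 100.
#'
#' @param m families x samples count matrix.
#' @return matrix of percentages.
#' @export
relative_abundance <- function(m) {
  .check_abundance(m)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  }
  sweep(m, 2, lib, "/") * 100
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Each sample is scaled by the sum of its counts up to the chosen quantile
#' of its nonzero-count distribution, then rescaled by the median scale
#' factor so normalized counts stay on a count-like scale.
#' `quantile = "auto"` picks the quantile data-adaptively: across a grid of
#' quantiles it tracks the median absolute deviation of per-sample quantiles
#' from their across-sample median and selects the first grid point past
#' which that stability curve changes by more than 10% relative - the
#' instability heuristic of the CSS method (falls back to 0.5 when no
#' crossing is found).
#'
#' @param m families x samples count matrix; every sample needs at least one
#'   nonzero count.
#' @param quantile a fraction in (0, 1] or `"auto"`.
#' @param log2_transform if `TRUE`, returns `log2(normalized + 1)`.
#' @return list with `normalized` (matrix), `scale_factors` (per sample) and
#'   `quantile` (the value used). With `quantile = 1` CSS collapses to
#'   total-sum scaling.
#' @export
css_normalize <- function(m, quantile = "auto", log2_transform = FALSE) {
  .check_abundance(m)
  if (any(colSums(m) == 0)) {
    stop("CSS is undefined for all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  }
  if (identical(quantile, "auto")) quantile <- .css_auto_quantile(m)
  stopifnot(is.numeric(quantile), quantile > 0, quantile <= 1)
  factors <- apply(m, 2, function(x) {
    nz <- x[x > 0]
    q <- stats::quantile(nz, probs = quantile, type = 7, names = FALSE)
    sum(nz[nz <= q])
  })
  normalized <- sweep(m, 2, factors, "/") * stats::median(factors)
  if (log2_transform) normalized <- log2(normalized + 1)
  list(normalized = normalized, scale_factors = factors, quantile = quantile)
}

# Stability heuristic for the CSS quantile: first grid point where the
# median absolute deviation of sample quantiles from the reference changes
# by > 10% relative to its current level.
.css_auto_quantile <- function(m, grid = seq(0.05, 1, by = 0.01)) {
  qs <- apply(m, 2, function(x) {
    stats::quantile(x[x > 0], probs = grid, type = 7, names = FALSE)
  })  # grid x samples
  ref <- apply(qs, 1, stats::median)
  dev <- apply(abs(qs - ref), 1, stats::median)
  rel <- abs(diff(dev)) / pmax(dev[-1], .Machine$double.eps)
  hit <- which(rel > 0.1)
  if (length(hit) == 0) return(0.5)
  grid[hit[1]]
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over nonzero proportions, in nats.
#'
#' @param counts count (or proportion) vector for one sample.
#' @return Shannon H.
#' @export
shannon_index <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("shannon_index() needs a nonzero library")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, with F1 the singleton and F2
#' the doubleton count. Requires integer counts (Chao1 is undefined
#' otherwise).
#'
#' @param counts integer count vector for one sample.
#' @return estimated richness.
#' @export
chao1_index <- function(counts) {
  stopifnot(all(counts >= 0))
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("Chao1 is undefined for non-integer counts")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample diversity table
#'
#' @param m families x samples integer count matrix.
#' @return data frame with `sample`, `observed`, `shannon`, `chao1`.
#' @export
diversity_table <- function(m) {
  .check_abundance(m)
  data.frame(
    sample = colnames(m),
    observed = colSums(m > 0),
    shannon = apply(m, 2, shannon_index),
    chao1 = apply(m, 2, chao1_index),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(j, k) = 1 - 2 * sum(min(x_ij, x_ik)) / (sum(x_ij) + sum(x_ik))`;
#' symmetric with zero diagonal, values in `[0, 1]`.
#'
#' @param m families x samples matrix with at least two samples.
#' @return samples x samples distance matrix.
#' @export
bray_curtis <- function(m) {
  .check_abundance(m)
  if (ncol(m) < 2) stop("bray_curtis() needs at least 2 samples")
  if (any(colSums(m) == 0)) {
    stop("Bray-Curtis is undefined for zero-library sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Sex-stratified Spearman association of a diversity index with a trait
#'
#' Spearman rank correlation (tie-corrected, two-sided) of `index` with
#' `trait`, computed overall and within each sex stratum. Strata with a
#' constant trait or index get `NA` with a flag.
#'
#' @param index per-subject diversity values (e.g. the `shannon` column of
#'   [diversity_table()]).
#' @param trait numeric trait (e.g. BMI or GRS).
#' @param sex factor aligned with `index`.
#' @return data frame with `stratum`, `n`, `rho`, `p`, `degenerate`.
#' @export
diversity_association <- function(index, trait, sex) {
  stopifnot(length(index) == length(trait), length(index) == length(sex))
  sex <- factor(sex)
  strata <- c(list(all = rep(TRUE, length(index))),
              stats::setNames(lapply(levels(sex), function(s) sex == s),
                              levels(sex)))
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]] & !is.na(index) & !is.na(trait)
    if (sum(sel) < 3) stop("stratum '", nm, "' has fewer than 3 subjects")
    if (stats::sd(index[sel]) == 0 || stats::sd(trait[sel]) == 0) {
      return(data.frame(stratum = nm, n = sum(sel), rho = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    }
    st <- spearman_test(index[sel], trait[sel])
    data.frame(stratum = nm, n = sum(sel), rho = st$rho, p = st$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
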