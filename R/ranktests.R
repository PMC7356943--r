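# Nonparametric rank tests with exact small-sample permutation p-values.
#
# All tests use midranks and tie correction. Exact p-values enumerate the
# full permutation distribution of the statistic and count permutations at
# least as extreme as the observed value (a 1e-9 guard absorbs floating-point
# noise in tied statistics). Asymptotic p-values use the tie-corrected
# chi-square / normal / t approximations.

# All distinct ways to assign `sizes` group labels to seq_len(sum(sizes)).
# Returns an integer matrix, one assignment per row (values 1..k).
.group_assignments <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  rec <- function(remaining, label) {
    if (label == k) {
      m <- matrix(remaining, nrow = 1)
      colnames(m) <- NULL
      return(list(m))
    }
    out <- list()
    picks <- utils::combn(remaining, sizes[label], simplify = FALSE)
    for (p in picks) {
      rest <- setdiff(remaining, p)
      for (tail in rec(rest, label + 1L)) {
        out[[length(out) + 1L]] <- cbind(matrix(p, nrow = 1), tail)
      }
    }
    out
  }
  parts <- rec(seq_len(n), 1L)
  assign_one <- function(row) {
    g <- integer(n)
    idx <- 1L
    for (label in seq_len(k)) {
      g[row[idx:(idx + sizes[label] - 1L)]] <- label
      idx <- idx + sizes[label]
    }
    g
  }
  t(vapply(parts, function(p) assign_one(as.integer(p)), integer(n)))
}

# All n! permutations of seq_len(n), built by insertion.
.all_permutations <- function(n) {
  stopifnot(n >= 1)
  perms <- matrix(1L, nrow = 1, ncol = 1)
  for (m in seq_len(n)[-1]) {
    new <- matrix(0L, nrow = nrow(perms) * m, ncol = m)
    r <- 1L
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(m)) {
        new[r, ] <- append(perms[i, ], m, after = pos - 1L)
        r <- r + 1L
      }
    }
    perms <- new
  }
  perms
}

# Tie-corrected Kruskal-Wallis H from a rank vector and integer group labels.
.kw_statistic <- function(r, g, n) {
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)  # all observations tied
  h / corr
}

#' Kruskal-Wallis rank test with exact small-sample option
#'
#' Tie-corrected Kruskal-Wallis test of a numeric response across two or more
#' groups. For small samples the exact permutation distribution of the
#' statistic is enumerated; otherwise the chi-square approximation with
#' `k - 1` degrees of freedom is used.
#'
#' @param x numeric response.
#' @param g group labels (coerced to factor); `NA` pairs are dropped.
#' @param exact logical; `NULL` (default) enumerates exactly when the total
#'   sample size is at most `exact_n_max`.
#' @param exact_n_max largest n for which the automatic rule enumerates.
#' @return list with `statistic`, `df`, `p.value`, `exact`, `n`.
#' @examples
#' kw_test(c(1, 3, 2, 6, 5, 4), rep(c("a", "b"), each = 3))
#' @export
kw_test <- function(x, g, exact = NULL, exact_n_max = 9L) {
  keep <- !(is.na(x) | is.na(g))
  x <- x[keep]
  g <- factor(g[keep])
  g <- droplevels(g)
  n <- length(x)
  k <- nlevels(g)
  if (n < 2 || k < 2) stop("kw_test() needs at least two groups with data")
  if (is.null(exact)) exact <- n <= exact_n_max
  r <- rank(x)
  gi <- as.integer(g)
  h <- .kw_statistic(r, gi, n)
  if (length(unique(r)) == 1L) {
    return(list(statistic = 0, df = k - 1L, p.value = 1, exact = FALSE, n = n))
  }
  if (exact) {
    sizes <- as.integer(table(gi))
    # enumerate label assignments; ranks are fixed, labels permute
    assignments <- .group_assignments(sizes)
    stats <- apply(assignments, 1L, function(lab) .kw_statistic(r, lab, n))
    p <- mean(stats >= h - 1e-9)
  } else {
    p <- stats::pchisq(h, df = k - 1L, lower.tail = FALSE)
  }
  list(statistic = h, df = k - 1L, p.value = min(1, p), exact = exact, n = n)
}

#' Mann-Whitney U test (two-sided) with exact small-sample option
#'
#' Two-group rank-sum test using midranks. The two-sided p-value is based on
#' the distance of U from its null mean: exactly, by enumerating all group
#' assignments; asymptotically, by the tie-corrected normal approximation
#' without continuity correction (so that the two-group Kruskal-Wallis
#' chi-square p equals this p).
#'
#' @inheritParams kw_test
#' @return list with `statistic` (U for the first group level), `p.value`,
#'   `exact`, `n`.
#' @export
mw_test <- function(x, g, exact = NULL, exact_n_max = 9L) {
  keep <- !(is.na(x) | is.na(g))
  x <- x[keep]
  g <- droplevels(factor(g[keep]))
  if (nlevels(g) != 2L) stop("mw_test() needs exactly two groups")
  n <- length(x)
  if (is.null(exact)) exact <- n <= exact_n_max
  r <- rank(x)
  n1 <- sum(g == levels(g)[1])
  n2 <- n - n1
  u_of <- function(idx1) sum(r[idx1]) - n1 * (n1 + 1) / 2
  u <- u_of(which(g == levels(g)[1]))
  mu <- n1 * n2 / 2
  if (length(unique(r)) == 1L) {
    return(list(statistic = u, p.value = 1, exact = FALSE, n = n))
  }
  if (exact) {
    subsets <- utils::combn(n, n1, simplify = FALSE)
    d <- vapply(subsets, function(s) abs(u_of(s) - mu), numeric(1))
    p <- mean(d >= abs(u - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = u, p.value = 1, exact = FALSE, n = n))
    z <- (u - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p.value = min(1, p), exact = exact, n = n)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho computed as the Pearson correlation of midranks. The
#' two-sided p-value enumerates all permutations of one margin when n is
#' small, and otherwise uses the t approximation on `n - 2` degrees of
#' freedom (valid with ties).
#'
#' @param x,y numeric vectors of equal length; `NA` pairs dropped.
#' @param exact logical; `NULL` enumerates when `n <= exact_n_max`.
#' @param exact_n_max largest n enumerated under the automatic rule.
#' @return list with `rho`, `p.value`, `exact`, `n`.
#' @export
spearman_test <- function(x, y, exact = NULL, exact_n_max = 8L) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_test() needs at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p.value = NA_real_, exact = FALSE, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= exact_n_max
  if (exact) {
    perms <- .all_permutations(n)
    # correlation of rx with each permutation of ry
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2))
    rhos <- apply(perms, 1L, function(p) {
      ryp <- ry[p]
      ryc <- ryp - mean(ryp)
      sum(rxc * ryc) / (denom * sqrt(sum(ryc^2)))
    })
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p.value = min(1, p), exact = exact, n = n)
}
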