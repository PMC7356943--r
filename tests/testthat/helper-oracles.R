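# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's internal enumeration code: label
# assignments come from utils::combn compositions, permutations from a
# recursive generator, and statistics from base R tests where possible.

# all permutations of 1..n, recursively
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# all relabelings of a two-group split: returns list of index vectors for
# group 1
oracle_two_group_splits <- function(n, n1) {
  utils::combn(n, n1, simplify = FALSE)
}

# exact Kruskal-Wallis p by enumerating group assignments; statistic taken
# from stats::kruskal.test (tie-corrected)
oracle_kw_exact_p <- function(x, g) {
  g <- factor(g)
  sizes <- as.integer(table(g))
  n <- length(x)
  obs <- unname(stats::kruskal.test(x, g)$statistic)
  results <- c()
  rec <- function(remaining, k, lab) {
    if (k == length(sizes)) {
      lab[remaining] <- k
      results <<- c(results,
                    unname(stats::kruskal.test(x, factor(lab))$statistic))
      return(invisible())
    }
    for (pick in utils::combn(remaining, sizes[k], simplify = FALSE)) {
      lab2 <- lab
      lab2[pick] <- k
      rec(setdiff(remaining, pick), k + 1L, lab2)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  mean(results >= obs - 1e-9)
}

# exact two-sided Mann-Whitney p: distance of W from its mean over all
# splits; statistic from stats::wilcox.test
oracle_mw_exact_p <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  n1 <- sum(g == levels(g)[1])
  mu <- n1 * (n - n1) / 2
  w_of <- function(idx1) {
    suppressWarnings(unname(stats::wilcox.test(x[idx1], x[-idx1],
                                               exact = FALSE)$statistic))
  }
  obs <- abs(w_of(which(g == levels(g)[1])) - mu)
  d <- vapply(oracle_two_group_splits(n, n1),
              function(s) abs(w_of(s) - mu), numeric(1))
  mean(d >= obs - 1e-9)
}

# exact two-sided Spearman p over all permutations of y
oracle_spearman_exact_p <- function(x, y) {
  obs <- abs(stats::cor(x, y, method = "spearman"))
  perms <- oracle_perms(length(y))
  rhos <- apply(perms, 1, function(p) {
    stats::cor(x, y[p], method = "spearman")
  })
  mean(abs(rhos) >= obs - 1e-9)
}

# normal-equation least squares with classical standard errors
oracle_ols <- function(y, X) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)[, 1]
  res <- y - as.vector(X %*% beta)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = beta, se = sqrt(diag(solve(xtx)) * s2))
}

# pooled-variance two-sample z test on the group-mean difference (equals the
# OLS dummy-variable test with a normal reference)
oracle_two_sample_z <- function(y, group) {
  y1 <- y[group == 1]
  y0 <- y[group == 0]
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)) /
    (length(y) - 2)
  d <- mean(y1) - mean(y0)
  se <- sqrt(sp2 * (1 / length(y1) + 1 / length(y0)))
  list(diff = d, se = se, z = d / se, p = 2 * stats::pnorm(-abs(d / se)))
}

# small deterministic count fixture, families x samples
fixture_counts <- function(seed = 1, n_families = 12, n_samples = 20) {
  set.seed(seed)
  m <- matrix(rnbinom(n_families * n_samples, mu = 50, size = 1),
              n_families, n_samples,
              dimnames = list(paste0("F", seq_len(n_families)),
                              paste0("S", seq_len(n_samples))))
  m[1, ] <- m[1, ] + 5  # keep at least one family always present
  storage.mode(m) <- "integer"
  m
}
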