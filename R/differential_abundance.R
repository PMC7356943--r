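# Two-group family-level discovery:
#  - Kruskal-Wallis screen + bootstrapped LDA effect size (LEfSe-style core)
#  - zero-inflated Gaussian regression on CSS-normalized log2 counts with
#    BH-FDR (metagenomeSeq-style)
#  - random-forest mean-decrease-accuracy ranking with ROC validation.

.two_classes <- function(labels) {
  cls <- if (is.factor(labels)) {
    levels(droplevels(labels))
  } else {
    # first-occurrence order: invariant under renaming the class labels
    unique(as.character(labels[!is.na(labels)]))
  }
  if (length(cls) != 2) stop("exactly two classes are required (got ",
                             length(cls), ")")
  cls
}

#' Per-family Kruskal-Wallis test between two classes
#'
#' Tie-corrected Kruskal-Wallis p per family (equivalent to the two-sided
#' Mann-Whitney test for two classes). Constant families get p = 1.
#'
#' @param features families x samples numeric matrix (percent scale or
#'   counts).
#' @param labels two-class vector of length `ncol(features)`.
#' @return data frame with `family`, `statistic`, `p`.
#' @export
kw_class_test <- function(features, labels) {
  stopifnot(ncol(features) == length(labels))
  .two_classes(labels)
  res <- apply(features, 1, function(x) {
    kt <- kw_test(x, labels, exact = FALSE)
    c(kt$statistic, kt$p.value)
  })
  data.frame(family = rownames(features), statistic = res[1, ], p = res[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LDA effect size (LEfSe-style two-class core)
#'
#' Families passing a Kruskal-Wallis screen at `alpha` are scored on data
#' rescaled to one million per sample. Over `n_boot` stratified bootstrap
#' rounds the one-dimensional discriminant effect (the class-mean difference
#' along the feature's discriminant axis) is averaged, and the LDA score is
#' `log10(10 + |mean effect| / 2)`. A family is flagged as a biomarker when
#' its screen p is below `alpha` and its score reaches `lda_min`.
#'
#' @param features families x samples matrix, per-sample composition
#'   (percent or proportions; rescaled internally).
#' @param labels two-class vector.
#' @param alpha Kruskal-Wallis screen threshold (default 0.05).
#' @param lda_min LDA score threshold (default 2.0).
#' @param n_boot bootstrap rounds (default 30).
#' @param seed integer seed for the bootstrap.
#' @return data frame with `family`, `kw_p`, `enriched` (class with the
#'   higher mean), `lda_score`, `passes_threshold`.
#' @export
lda_effect_size <- function(features, labels, alpha = 0.05, lda_min = 2.0,
                            n_boot = 30, seed = 1) {
  cls <- .two_classes(labels)
  idx1 <- which(labels == cls[1])
  idx2 <- which(labels == cls[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("each class needs at least 2 samples")
  }
  scaled <- sweep(features, 2, colSums(features), "/") * 1e6
  kw <- kw_class_test(features, labels)
  m1 <- rowMeans(scaled[, idx1, drop = FALSE])
  m2 <- rowMeans(scaled[, idx2, drop = FALSE])
  enriched <- ifelse(m1 >= m2, cls[1], cls[2])
  set.seed(seed)
  eff <- matrix(NA_real_, nrow = nrow(features), ncol = n_boot)
  for (b in seq_len(n_boot)) {
    b1 <- sample(idx1, replace = TRUE)
    b2 <- sample(idx2, replace = TRUE)
    eff[, b] <- rowMeans(scaled[, b1, drop = FALSE]) -
      rowMeans(scaled[, b2, drop = FALSE])
  }
  mean_eff <- rowMeans(eff)
  score <- log10(10 + abs(mean_eff) / 2)
  score[kw$p >= alpha] <- NA_real_  # only screened families are scored
  data.frame(family = rownames(features), kw_p = kw$p, enriched = enriched,
             lda_score = score,
             passes_threshold = !is.na(score) & score >= lda_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

# One-family zero-inflated Gaussian EM fit.
# y: log2 CSS values; zero: logical (raw count == 0); loglib: log library
# size; group: 0/1. Returns coefficients, SE, convergence and the
# log-likelihood trace.
.zig_em_one <- function(y, zero, loglib, group, tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  X <- cbind(1, group)
  w <- ifelse(zero, 0.5, 1)  # posterior probability of the Gaussian component
  pi_hat <- rep(mean(zero) * 0.5 + 1e-6, n)
  ll_trace <- numeric(0)
  converged <- FALSE
  beta <- c(mean(y), 0)
  sigma <- max(stats::sd(y), 1e-3)
  for (it in seq_len(max_iter)) {
    # M step: weighted least squares for the Gaussian part
    xtwx <- crossprod(X, X * w)
    beta <- solve(xtwx, crossprod(X, y * w))[, 1]
    mu <- as.vector(X %*% beta)
    sigma <- sqrt(max(sum(w * (y - mu)^2) / sum(w), 1e-12))
    # M step: logistic zero model on log library size
    if (any(zero)) {
      fit <- suppressWarnings(try(stats::glm(
        (1 - w) ~ loglib, family = stats::quasibinomial()), silent = TRUE))
      pi_hat <- if (inherits(fit, "try-error") || !fit$converged) {
        rep(min(max(mean(1 - w), 1e-6), 1 - 1e-6), n)
      } else {
        stats::fitted(fit)
      }
    } else {
      pi_hat <- rep(1e-12, n)
    }
    # E step + observed-data log-likelihood
    dens <- stats::dnorm(y, mu, sigma)
    comp <- ifelse(zero, pi_hat + (1 - pi_hat) * dens, (1 - pi_hat) * dens)
    ll <- sum(log(pmax(comp, 1e-300)))
    w_new <- ifelse(zero, (1 - pi_hat) * dens / pmax(comp, 1e-300), 1)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      w <- w_new
      break
    }
    w <- w_new
  }
  # SE of the group coefficient from the weighted normal equations with the
  # unbiased residual variance
  mu <- as.vector(X %*% beta)
  df <- max(sum(w) - ncol(X), 1)
  s2 <- sum(w * (y - mu)^2) / df
  cov <- solve(crossprod(X, X * w)) * s2
  se <- sqrt(diag(cov))[2]
  list(beta = beta[2], se = se, converged = converged, ll_trace = ll_trace,
       sigma = sigma)
}

#' Zero-inflated Gaussian differential abundance
#'
#' Per family, fits a mixture of a point mass at zero (whose weight follows
#' a logistic model on log library size, capturing depth-dependent dropout)
#' and a Gaussian on `log2(CSS-normalized count + 1)` with a two-class group
#' mean shift, by EM (log-likelihood tolerance 1e-8, at most 100
#' iterations). The group coefficient is tested with a z-test weighted by
#' posterior non-zero membership; q-values are Benjamini-Hochberg across
#' families. For a zero-free family the mixture collapses to an ordinary
#' two-sample regression z-test.
#'
#' @param m families x samples raw count matrix.
#' @param labels two-class vector; the coefficient is the log2 shift of the
#'   second class relative to the first.
#' @param css_quantile passed to [css_normalize()].
#' @return data frame with `family`, `coefficient`, `se`, `z`, `p`, `q`,
#'   `n_zero`, `converged`, `skipped`; the per-family log-likelihood traces
#'   are in the `ll_traces` attribute.
#' @export
zig_fit <- function(m, labels, css_quantile = "auto") {
  .check_abundance(m)
  cls <- .two_classes(labels)
  if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
  css <- css_normalize(m, quantile = css_quantile)
  y_mat <- log2(css$normalized + 1)
  loglib <- log(colSums(m))
  group <- as.numeric(labels == cls[2])
  traces <- vector("list", nrow(m))
  names(traces) <- rownames(m)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    zero <- m[i, ] == 0
    if (all(zero)) {
      return(data.frame(family = rownames(m)[i], coefficient = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        n_zero = sum(zero), converged = NA, skipped = TRUE))
    }
    fit <- .zig_em_one(y_mat[i, ], zero, loglib, group)
    traces[[i]] <<- fit$ll_trace
    if (!fit$converged) {
      warning("ZIG EM did not converge for family ", rownames(m)[i],
              "; last iterate reported")
    }
    data.frame(family = rownames(m)[i], coefficient = fit$beta, se = fit$se,
               z = fit$beta / fit$se,
               p = 2 * stats::pnorm(-abs(fit$beta / fit$se)),
               n_zero = sum(zero), converged = fit$converged, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[!out$skipped] <- bh_adjust(out$p[!out$skipped])
  rownames(out) <- NULL
  attr(out, "ll_traces") <- traces
  attr(out, "css_quantile") <- css$quantile
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; `q >= p` and
#' `max(q) <= 1`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Random-forest importance ranking with ROC validation
#'
#' Repeats a 500-tree random forest classifier on stratified 70% training
#' splits, collecting each family's out-of-bag permutation importance (mean
#' decrease in accuracy, unscaled) and the ROC AUC of the class probability
#' on the 30% holdout. Families are ranked by mean MDA across repeats.
#'
#' @param features families x samples matrix (percent scale).
#' @param labels two-class vector; at least 10 samples per class.
#' @param n_trees trees per forest (default 500).
#' @param n_repeats independent train/validate repeats (default 10).
#' @param train_frac training fraction (default 0.70).
#' @param seed integer seed.
#' @return list of class `rf_ranking`: `ranking` (data frame `family`,
#'   `mean_mda`, `rank`), `mda` (repeats x families matrix), `auc` (one AUC
#'   per repeat).
#' @export
rf_rank <- function(features, labels, n_trees = 500, n_repeats = 10,
                    train_frac = 0.70, seed = 1) {
  cls <- .two_classes(labels)
  y <- factor(as.character(labels), levels = cls)
  if (min(table(y)) < 10) stop("each class needs at least 10 samples")
  x <- as.data.frame(t(features))
  colnames(x) <- make.names(rownames(features))
  set.seed(seed)
  mda <- matrix(NA_real_, nrow = n_repeats, ncol = nrow(features),
                dimnames = list(NULL, rownames(features)))
  auc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    repeat {
      train <- unlist(lapply(cls, function(cl) {
        idx <- which(y == cl)
        sample(idx, max(2, floor(train_frac * length(idx))))
      }))
      test <- setdiff(seq_along(y), train)
      if (min(table(y[train])) >= 2 && length(unique(y[test])) == 2) break
      warning("degenerate split resampled in repeat ", r)
    }
    fit <- randomForest::randomForest(x = x[train, , drop = FALSE],
                                      y = y[train], ntree = n_trees,
                                      importance = TRUE)
    mda[r, ] <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    prob <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, cls[2]]
    auc[r] <- roc_auc(prob, y[test])
  }
  mean_mda <- colMeans(mda)
  ranking <- data.frame(family = rownames(features), mean_mda = mean_mda,
                        rank = rank(-mean_mda, ties.method = "first"),
                        row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$rank), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, mda = mda, auc = auc),
            class = "rf_ranking")
}

#' ROC area under the curve via the rank statistic
#'
#' Tie-aware Mann-Whitney formulation: the probability that a random member
#' of the positive class scores above a random member of the negative class
#' (ties counted half). The positive class is the second class by first
#' occurrence in `labels` (or the second level of a factor).
#'
#' @param scores numeric classifier scores.
#' @param labels two-class vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  cls <- .two_classes(labels)
  pos <- labels == cls[2]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
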