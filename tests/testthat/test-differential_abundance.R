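# LEfSe-style effect sizes, zero-inflated Gaussian fits, BH adjustment,
# random-forest ranking and ROC AUC.

test_that("the per-family class test behaves like a two-group rank test", {
  set.seed(15)
  feats <- fixture_counts(15, n_families = 6, n_samples = 30)
  labels <- rep(c("lo", "hi"), 15)
  res <- kw_class_test(feats, labels)
  for (i in 1:6) {
    expect_equal(res$p[i], mw_test(feats[i, ], labels, exact = FALSE)$p.value,
                 tolerance = 1e-10)
  }
  feats[2, ] <- 7
  expect_equal(kw_class_test(feats, labels)$p[2], 1)
  expect_error(kw_class_test(feats, rep("one", 30)), "two classes")
})

test_that("a planted family dominates the LDA effect-size ranking", {
  set.seed(16)
  n <- 40
  labels <- rep(c("normal", "obese"), each = n / 2)
  feats <- matrix(rlnorm(20 * n, 3, 0.6), nrow = 20,
                  dimnames = list(paste0("F", 1:20), paste0("S", 1:n)))
  # disjoint class supports with a ten-fold mean ratio
  feats["F7", ] <- c(runif(n / 2, 1, 2), runif(n / 2, 15, 25))
  res <- lda_effect_size(relative_abundance(round(feats * 10)), labels,
                         seed = 1)
  expect_true(res$passes_threshold[res$family == "F7"])
  expect_equal(res$family[which.max(res$lda_score)], "F7")
  expect_identical(res$enriched[res$family == "F7"], "obese")
})

test_that("swapping class labels flips enrichment but not scores", {
  set.seed(17)
  feats <- fixture_counts(17, n_families = 10, n_samples = 24)
  feats[3, 1:12] <- feats[3, 1:12] + 60L
  labels <- rep(c("g1", "g2"), each = 12)
  swapped <- ifelse(labels == "g1", "g2", "g1")
  a <- lda_effect_size(feats, labels, seed = 5)
  b <- lda_effect_size(feats, swapped, seed = 5)
  expect_equal(a$lda_score, b$lda_score)
  expect_equal(a$kw_p, b$kw_p)
  keep <- !is.na(a$lda_score)
  expect_true(all(a$enriched[keep] != b$enriched[keep]))
})

test_that("null LDA effect sizes pass at roughly the screen rate", {
  set.seed(18)
  passes <- 0; total <- 0
  for (s in 1:30) {
    feats <- matrix(rlnorm(10 * 30, 4, 0.7), nrow = 10,
                    dimnames = list(paste0("F", 1:10), NULL))
    labels <- rep(c("a", "b"), 15)
    res <- lda_effect_size(feats, labels, seed = s)
    passes <- passes + sum(res$passes_threshold)
    total <- total + nrow(res)
  }
  rate <- passes / total
  expect_lt(rate, 0.10)   # near the 0.05 screen level
  expect_gt(rate, 0.005)  # and not degenerate
})

test_that("ZIG collapses to the pooled two-sample z-test on zero-free data", {
  set.seed(19)
  n <- 30
  m <- matrix(rpois(8 * n, 60) + 1L, nrow = 8,
              dimnames = list(paste0("F", 1:8), paste0("S", 1:n)))
  labels <- rep(c("c1", "c2"), n / 2)
  fit <- zig_fit(m, labels, css_quantile = 0.5)
  y <- log2(css_normalize(m, 0.5)$normalized + 1)
  group <- as.numeric(labels == "c2")
  for (i in 1:8) {
    z <- oracle_two_sample_z(y[i, ], group)
    expect_equal(fit$coefficient[i], z$diff, tolerance = 1e-6)
    expect_equal(fit$se[i], z$se, tolerance = 1e-6)
    expect_equal(fit$p[i], z$p, tolerance = 1e-6)
  }
  expect_true(all(fit$converged))
})

test_that("ZIG recovers a planted four-fold shift under 20% zeros", {
  est <- se <- numeric(6)
  for (s in 1:6) {
    set.seed(100 + s)
    n <- 100  # 50 per class
    labels <- rep(c("lo", "hi"), each = 50)
    m <- matrix(rlnorm(30 * n, 5, 0.5), nrow = 30)
    m[7, labels == "hi"] <- m[7, labels == "hi"] * 4  # log2(4) = 2
    zero <- matrix(runif(30 * n) < 0.2, nrow = 30)
    m[zero] <- 0
    m <- round(m)
    storage.mode(m) <- "integer"
    rownames(m) <- paste0("F", 1:30)
    keep <- rowSums(m) > 0
    fit <- zig_fit(m[keep, ], labels, css_quantile = 0.75)
    est[s] <- fit$coefficient[fit$family == "F7"]
    se[s] <- fit$se[fit$family == "F7"]
  }
  expect_lt(abs(mean(est) - 2), 3 * mean(se) / sqrt(6))
})

test_that("the EM log-likelihood never decreases", {
  set.seed(20)
  sim <- simulate_cohort(cohort_config(n_subjects = 80, seed = 20))
  grp <- bmi_classify(sim$cohort$bmi, binary = TRUE)
  filtered <- suppressMessages(filter_features(sim$counts))
  fit <- zig_fit(filtered, grp)
  traces <- attr(fit, "ll_traces")
  traces <- traces[!vapply(traces, is.null, logical(1))]
  expect_gt(length(traces), 10)
  for (tr in traces) expect_true(all(diff(tr) >= -1e-6))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
})

test_that("random forest finds a perfect separator and is deterministic", {
  set.seed(22)
  n <- 60
  labels <- rep(c("low", "high"), each = n / 2)
  feats <- matrix(rlnorm(30 * n, 3, 0.5), nrow = 30,
                  dimnames = list(paste0("F", 1:30), paste0("S", 1:n)))
  feats["F11", ] <- ifelse(labels == "high", runif(n, 10, 12),
                           runif(n, 1, 3))
  rf <- rf_rank(feats, labels, n_trees = 300, n_repeats = 10, seed = 7)
  expect_identical(rf$ranking$family[1], "F11")
  top_per_repeat <- apply(rf$mda, 1, function(r) names(which.max(r)))
  expect_gte(sum(top_per_repeat == "F11"), 9)
  expect_true(all(rf$auc > 0.9))
  rf2 <- rf_rank(feats, labels, n_trees = 300, n_repeats = 10, seed = 7)
  expect_identical(rf$ranking, rf2$ranking)
  expect_equal(rf$auc, rf2$auc)
})

test_that("null features have importance indistinguishable from zero", {
  set.seed(23)
  n <- 50
  labels <- rep(c("a", "b"), each = n / 2)
  feats <- matrix(rlnorm(15 * n, 3, 0.5), nrow = 15,
                  dimnames = list(paste0("F", 1:15), NULL))
  rf <- rf_rank(feats, labels, n_trees = 200, n_repeats = 8, seed = 3)
  se <- apply(rf$mda, 2, sd) / sqrt(nrow(rf$mda))
  expect_true(all(abs(rf$ranking$mean_mda) <=
                    3 * se[rf$ranking$family] + 1e-3))
})

test_that("ROC AUC is the tie-aware rank statistic", {
  labels <- rep(c("neg", "pos"), each = 5)
  expect_equal(roc_auc(c(1:5, 6:10), labels), 1)
  expect_equal(roc_auc(c(6:10, 1:5), labels), 0)
  set.seed(24)
  s <- rnorm(1000)
  l <- rep(c("neg", "pos"), 500)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.05)
  # complement identity on tie-free scores
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  # independent cross-check against pROC
  if (requireNamespace("pROC", quietly = TRUE)) {
    s2 <- rnorm(80)
    l2 <- factor(rep(c("neg", "pos"), 40), levels = c("neg", "pos"))
    expect_equal(roc_auc(s2, l2),
                 as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                                direction = "<",
                                                levels = c("neg", "pos")))))
  }
  expect_error(roc_auc(1:4, rep("pos", 4)), "two classes")
})
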