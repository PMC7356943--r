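# OLS engine, interaction regressions, predicted curves, WHO classes.

test_that("OLS matches the normal-equation oracle", {
  set.seed(25)
  for (i in 1:4) {
    X <- cbind(x1 = rnorm(20), x2 = rnorm(20), x3 = runif(20))
    y <- 1 + 2 * X[, 1] - 0.5 * X[, 3] + rnorm(20)
    fit <- fit_ols(y, X)
    oracle <- oracle_ols(y, cbind(1, X))
    expect_equal(fit$coefficients$estimate, unname(oracle$beta),
                 tolerance = 1e-10)
    expect_equal(fit$coefficients$se, unname(oracle$se), tolerance = 1e-10)
  }
  # exact linear relation
  x <- 1:10
  fit <- fit_ols(2 * x, cbind(x = x))
  expect_equal(fit$coefficients$estimate, c(0, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # rank deficiency names the collinear column
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), X), "collinear.*b")
  expect_error(fit_ols(rnorm(3), cbind(a = rnorm(3), b = rnorm(3),
                                       c = rnorm(3))), "more observations")
})

test_that("OLS agrees with stats::lm on an awkward fixture", {
  set.seed(26)
  X <- cbind(dose = rexp(40), age = rnorm(40, 50, 8))
  y <- 3 + 0.7 * X[, 1] + rnorm(40)
  fit <- fit_ols(y, X)
  lmfit <- summary(lm(y ~ dose + age, data = data.frame(X)))
  expect_equal(fit$coefficients$estimate, unname(coef(lmfit)[, 1]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$p, unname(coef(lmfit)[, 4]),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, lmfit$r.squared, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, lmfit$adj.r.squared, tolerance = 1e-12)
  expect_equal(unname(fit$f_statistic), unname(lmfit$fstatistic[1]),
               tolerance = 1e-10)
})

test_that("adding pure noise does not raise adjusted R-squared on average", {
  set.seed(27)
  delta <- replicate(400, {
    x <- rnorm(30)
    y <- x + rnorm(30)
    f1 <- fit_ols(y, cbind(x = x))
    f2 <- fit_ols(y, cbind(x = x, junk = rnorm(30)))
    f2$adj_r_squared - f1$adj_r_squared
  })
  expect_lte(mean(delta), 0.005)
})

test_that("95% confidence intervals cover planted coefficients at ~95%", {
  set.seed(28)
  covered <- replicate(400, {
    X <- cbind(x1 = rnorm(50), x2 = rnorm(50))
    y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(50)
    fit <- fit_ols(y, X)
    i <- 2  # x1
    half <- qt(0.975, fit$df_residual) * fit$coefficients$se[i]
    abs(fit$coefficients$estimate[i] - 0.5) <= half
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.985)
})

test_that("interaction models stratify by sex with the right design", {
  sim <- simulate_cohort(cohort_config(n_subjects = 300, seed = 29))
  ch <- sim$cohort
  cov <- ch[, c("sex", "age", "mets", "energy")]
  pooled <- interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs, cov,
                              stratum = "all")
  women <- interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs, cov,
                             stratum = "women")
  men <- interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs, cov,
                           stratum = "men")
  expect_true("sexfemale" %in% pooled$coefficients$term)
  expect_false("sexfemale" %in% women$coefficients$term)
  expect_false("sexfemale" %in% men$coefficients$term)
  expect_equal(women$n + men$n, pooled$n)
  expect_lte(pooled$adj_r_squared, pooled$r_squared)
  # with a female-only planted interaction, the pooled estimate sits between
  # the stratum estimates
  b <- function(f) f$coefficients$estimate[f$coefficients$term == "family:grs"]
  expect_true(b(pooled) >= min(b(men), b(women)) - 1e-9 &&
                b(pooled) <= max(b(men), b(women)) + 1e-9)
  expect_error(interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs,
                                 cov[, c("sex", "age", "mets")],
                                 stratum = "all"), "covariates")
})

test_that("a null interaction is estimated near zero", {
  cfg <- cohort_config(n_subjects = 5000, seed = 30,
                       interaction_beta_female = 0,
                       interaction_beta_male = 0)
  sim <- simulate_cohort(cfg)
  ch <- sim$cohort
  fit <- interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs,
                           ch[, c("sex", "age", "mets", "energy")], "all")
  co <- fit$coefficients
  est <- co$estimate[co$term == "family:grs"]
  expect_lt(abs(est), 3 * co$se[co$term == "family:grs"])
})

test_that("predicted curves obey linear-model algebra", {
  sim <- simulate_cohort(cohort_config(n_subjects = 400, seed = 31))
  ch <- sim$cohort
  fit <- interaction_model(ch$bmi, ch$focal_relabund, ch$true_grs,
                           ch[, c("sex", "age", "mets", "energy")], "women")
  curves <- predict_curve(fit, family_values = c(5, 15), grs_range = 0:10)
  expect_equal(nrow(curves), 22)
  b <- fit$coefficients
  bi <- b$estimate[b$term == "family:grs"]
  slope <- function(fv) {
    y <- curves$bmi_predicted[curves$family_value == fv]
    diff(y)[1]
  }
  expect_equal(slope(15) - slope(5), 10 * bi, tolerance = 1e-10)
  # zero interaction: parallel curves
  fit0 <- fit
  fit0$coefficients$estimate[fit0$coefficients$term == "family:grs"] <- 0
  c0 <- predict_curve(fit0)
  expect_equal(slope <- diff(c0$bmi_predicted[c0$family_value == 5]),
               diff(c0$bmi_predicted[c0$family_value == 15]),
               tolerance = 1e-10)
  expect_error(predict_curve(fit, family_values = c(5, 150)), "\\[0, 100\\]")
})

test_that("WHO classification uses half-open boundaries", {
  expect_identical(as.character(bmi_classify(24.0)), "normalweight")
  expect_identical(as.character(bmi_classify(27.0)), "overweight")
  expect_identical(as.character(bmi_classify(27.0, binary = TRUE)),
                   "overweight+obese")
  expect_identical(as.character(bmi_classify(31.7)), "obese")
  eps <- .Machine$double.eps * 32
  expect_identical(as.character(bmi_classify(25 - eps)), "normalweight")
  expect_identical(as.character(bmi_classify(25)), "overweight")
  expect_identical(as.character(bmi_classify(30)), "obese")
  expect_error(bmi_classify(0), "positive")
  expect_error(bmi_classify(-3), "positive")
})
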