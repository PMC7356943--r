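# Interaction regressions: BMI ~ family abundance x GRS + covariates,
# pooled and sex-stratified, with predicted-BMI curves and WHO BMI classes.

#' Ordinary least squares with full inference
#'
#' QR-based least squares with coefficient standard errors from the
#' unbiased residual variance, t-tests, R-squared, adjusted R-squared
#' (`1 - (1 - R2) * (n - 1) / (n - p - 1)`) and the overall F test.
#'
#' @param y response vector.
#' @param design numeric matrix with named columns (predictors).
#' @param intercept prepend an intercept column (default `TRUE`).
#' @return object of class `ols_fit`: `coefficients` data frame (`term`,
#'   `estimate`, `se`, `t`, `p`), `r_squared`, `adj_r_squared`,
#'   `f_statistic`, `model_p`, `n`, `df_residual`, `sigma`, plus `fitted`
#'   and `residuals`.
#' @export
fit_ols <- function(y, design, intercept = TRUE) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  X <- if (intercept) cbind("(Intercept)" = 1, design) else design
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations (", n, ") than parameters (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - rss / tss
  k_model <- p - as.integer(intercept)  # predictors excluding intercept
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k_model - 1)
  fstat <- if (k_model > 0) ((tss - rss) / k_model) / sigma2 else NA_real_
  model_p <- if (k_model > 0) {
    stats::pf(fstat, k_model, df, lower.tail = FALSE)
  } else NA_real_
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = as.numeric(beta),
                              se = se, t = as.numeric(tval),
                              p = as.numeric(pval), row.names = NULL,
                              stringsAsFactors = FALSE),
    r_squared = r2, adj_r_squared = adj_r2, f_statistic = fstat,
    model_p = model_p, n = n, df_residual = df, sigma = sqrt(sigma2),
    fitted = fitted, residuals = res), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit: n =", x$n, " R2 =", signif(x$r_squared, 4),
      " adjR2 =", signif(x$adj_r_squared, 4),
      " model p =", format.pval(x$model_p), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

.coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("term '", term, "' not in the model")
  fit$coefficients$estimate[i]
}

#' Family-by-GRS interaction regression on BMI
#'
#' Fits `BMI ~ family + GRS + family:GRS + age + METs + energy`, adding a
#' sex term only for the pooled model (`stratum = "all"`); sex-stratified
#' models drop it. The family abundance enters on the percent scale.
#'
#' @param bmi BMI vector (kg/m2).
#' @param family_relabund family relative abundance, percent.
#' @param grs genetic risk score.
#' @param covariates data frame with `sex` (factor, levels containing
#'   "female"/"male"), `age`, `mets`, `energy`.
#' @param stratum `"all"`, `"men"` or `"women"`.
#' @param family_name label used for the abundance term (default
#'   `"family"`).
#' @return `ols_fit` with extra fields `stratum`, `family_name` and
#'   `covariate_means` (the stratum means used by [predict_curve()]).
#' @export
interaction_model <- function(bmi, family_relabund, grs, covariates,
                              stratum = c("all", "men", "women"),
                              family_name = "family") {
  stratum <- match.arg(stratum)
  n <- length(bmi)
  stopifnot(length(family_relabund) == n, length(grs) == n,
            nrow(covariates) == n)
  needed <- c("sex", "age", "mets", "energy")
  if (!all(needed %in% names(covariates))) {
    stop("covariates must contain: ", paste(needed, collapse = ", "))
  }
  sel <- switch(stratum,
                all = rep(TRUE, n),
                men = covariates$sex == "male",
                women = covariates$sex == "female")
  sel <- sel & !is.na(grs) & !is.na(bmi) & !is.na(family_relabund)
  if (!any(sel)) stop("stratum '", stratum, "' is empty")
  X <- cbind(family_relabund[sel], grs[sel],
             family_relabund[sel] * grs[sel],
             covariates$age[sel], covariates$mets[sel],
             covariates$energy[sel])
  colnames(X) <- c(family_name, "grs", paste0(family_name, ":grs"),
                   "age", "mets", "energy")
  if (stratum == "all") {
    X <- cbind(X, sexfemale = as.numeric(covariates$sex[sel] == "female"))
  }
  fit <- fit_ols(bmi[sel], X)
  fit$stratum <- stratum
  fit$family_name <- family_name
  fit$covariate_means <- colMeans(X[, setdiff(colnames(X),
                                              c(family_name, "grs",
                                                paste0(family_name, ":grs"))),
                                    drop = FALSE])
  fit
}

#' Predicted BMI curves over the GRS range
#'
#' Predicted BMI at fixed family abundance values (default 5% and 15%)
#' across a GRS grid, with the remaining covariates held at their stratum
#' means. The slope difference between two abundance curves equals
#' `(value2 - value1) * interaction beta` per GRS unit.
#'
#' @param fit an [interaction_model()] result.
#' @param family_values abundance values, percent, each in `[0, 100]`.
#' @param grs_range integer GRS grid (default `0:10`).
#' @return data frame with `family_value`, `grs`, `bmi_predicted`.
#' @export
predict_curve <- function(fit, family_values = c(5, 15), grs_range = 0:10) {
  stopifnot(inherits(fit, "ols_fit"))
  if (is.null(fit$family_name)) {
    stop("fit must come from interaction_model()")
  }
  if (any(family_values < 0 | family_values > 100)) {
    stop("family abundance values must lie in [0, 100] percent")
  }
  b0 <- .coef_of(fit, "(Intercept)")
  bf <- .coef_of(fit, fit$family_name)
  bg <- .coef_of(fit, "grs")
  bi <- .coef_of(fit, paste0(fit$family_name, ":grs"))
  base <- b0 + sum(vapply(names(fit$covariate_means), function(nm) {
    .coef_of(fit, nm) * fit$covariate_means[[nm]]
  }, numeric(1)))
  grid <- expand.grid(family_value = family_values, grs = grs_range)
  grid$bmi_predicted <- base + bf * grid$family_value + bg * grid$grs +
    bi * grid$family_value * grid$grs
  grid[order(grid$family_value, grid$grs), ]
}

#' WHO BMI classification
#'
#' Normal weight below 25, overweight in `[25, 30)`, obese at 30 and above
#' (standard half-open WHO intervals).
#'
#' @param bmi positive BMI values (kg/m2).
#' @param binary if `TRUE`, merge overweight and obese into a single
#'   `overweight+obese` class.
#' @return factor of class labels.
#' @export
bmi_classify <- function(bmi, binary = FALSE) {
  if (any(is.na(bmi)) || any(bmi <= 0)) {
    stop("BMI must be positive and non-missing")
  }
  cls <- cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
             labels = c("normalweight", "overweight", "obese"))
  if (binary) {
    cls <- factor(ifelse(cls == "normalweight", "normalweight",
                         "overweight+obese"),
                  levels = c("normalweight", "overweight+obese"))
  }
  cls
}
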