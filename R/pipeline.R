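# Pipeline orchestration and table readers/writers.
#
# All tables are TSV (header row, UTF-8, "." for missing). The manifest is
# JSON and, together with the seed, suffices to reproduce a run.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
}

#' Read a genotype-string TSV
#'
#' First column = subject id, remaining columns = one genotype string per
#' SNP ("." or empty = missing).
#'
#' @param path TSV path.
#' @return subjects x SNPs character matrix.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c(".", ""),
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read genotypes from a VCF
#'
#' Biallelic sites only; genotype categories are formed from the GT field
#' and REF/ALT alleles (phasing ignored, missing calls become `NA`).
#' Coordinates are irrelevant here - only the genotype categories are used.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return subjects x SNPs character matrix of genotype strings.
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  samples <- header[-(1:9)]
  out <- matrix(NA_character_, nrow = length(samples), ncol = length(body),
                dimnames = list(samples, vapply(body, `[`, "", 3)))
  for (j in seq_along(body)) {
    rec <- body[[j]]
    alt <- rec[5]
    if (grepl(",", alt, fixed = TRUE)) {
      stop("multiallelic site ", rec[3], " is not supported")
    }
    alleles <- c(rec[4], alt)
    gt <- sub(":.*", "", rec[-(1:9)])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    parts <- strsplit(gt, "/", fixed = TRUE)
    out[, j] <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_character_)
      paste(alleles[as.integer(p) + 1L], collapse = "")
    }, character(1))
  }
  out
}

#' Read a families x samples abundance TSV
#'
#' First column = family label, header row = sample ids, integer counts.
#'
#' @param path TSV path.
#' @return integer count matrix.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Pipeline run configuration
#'
#' One structured configuration object covering every stage. Defaults echo
#' the analysis parameters of the reference study where one is printed
#' (screen alpha 0.20, confirmation alpha 0.10, 10% category minimum, CSS
#' normalization, LDA threshold 2.0, 500 trees, 10 repeats, 70/30 split);
#' the remaining values are the package's documented gap-filling choices.
#'
#' @param outdir output directory for the run.
#' @param seed master seed; every stage derives its randomness from it.
#' @param stages named logical vector toggling `simulate`, `grs`,
#'   `diversity`, `diffabund`, `interact`.
#' @param cohort,microbiome [cohort_config()] / [microbiome_config()].
#' @param alpha1,merge_alpha,alpha2,min_frac,collinearity_r GRS-stage
#'   thresholds (see [build_grs()]).
#' @param css_quantile CSS quantile or `"auto"`.
#' @param lefse_alpha,lda_min,n_boot LDA-effect-size parameters.
#' @param rf_trees,rf_repeats,train_frac random-forest parameters.
#' @param family focal family for the interaction models.
#' @param inputs optional named list of input paths (`cohort`, `genotypes`,
#'   `abundance`) used when the simulate stage is disabled.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("microgrs_run_"), seed = 1L,
                       stages = c(simulate = TRUE, grs = TRUE,
                                  diversity = TRUE, diffabund = TRUE,
                                  interact = TRUE),
                       cohort = cohort_config(seed = seed),
                       microbiome = microbiome_config(),
                       alpha1 = 0.20, merge_alpha = 0.05, alpha2 = 0.10,
                       min_frac = 0.10, collinearity_r = 0.8,
                       css_quantile = "auto",
                       lefse_alpha = 0.05, lda_min = 2.0, n_boot = 30,
                       rf_trees = 500, rf_repeats = 10, train_frac = 0.70,
                       family = "Prevotellaceae", inputs = list()) {
  default_stages <- c(simulate = TRUE, grs = TRUE, diversity = TRUE,
                      diffabund = TRUE, interact = TRUE)
  default_stages[names(stages)] <- stages
  stages <- default_stages
  for (v in c(alpha1, merge_alpha, alpha2, lefse_alpha)) {
    if (v <= 0 || v > 1) stop("significance thresholds must lie in (0, 1]")
  }
  stopifnot(min_frac >= 0, min_frac < 0.5,
            collinearity_r > 0, collinearity_r <= 1,
            train_frac > 0, train_frac < 1,
            rf_trees >= 1, rf_repeats >= 1, n_boot >= 1, lda_min >= 0)
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 cohort = cohort, microbiome = microbiome, alpha1 = alpha1,
                 merge_alpha = merge_alpha, alpha2 = alpha2,
                 min_frac = min_frac, collinearity_r = collinearity_r,
                 css_quantile = css_quantile, lefse_alpha = lefse_alpha,
                 lda_min = lda_min, n_boot = n_boot, rf_trees = rf_trees,
                 rf_repeats = rf_repeats, train_frac = train_frac,
                 family = family, inputs = inputs),
            class = "run_config")
}

#' Run the simulate -> GRS -> diversity -> differential abundance ->
#' interaction pipeline
#'
#' Executes the enabled stages in order and writes one TSV report per
#' product plus a JSON manifest. Stage dependencies are checked before any
#' compute; a stage failure halts the run with the stage name while earlier
#' outputs remain on disk. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage products and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  if (st["interact"] && !st["grs"]) {
    stop("configuration error: the interact stage requires the grs stage")
  }
  if (!st["simulate"] &&
      !all(c("cohort", "genotypes", "abundance") %in% names(config$inputs))) {
    stop("configuration error: with simulation disabled, inputs must name ",
         "'cohort', 'genotypes' and 'abundance' files")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(outdir = config$outdir)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (st["simulate"]) {
    run_stage("simulate", {
      cohort_cfg <- config$cohort
      cohort_cfg$seed <- config$seed
      sim <- simulate_cohort(cohort_cfg, default_snp_specs(),
                             config$microbiome)
      out$sim <- sim
      .write_tsv(cbind(sim$cohort,
                       as.data.frame(sim$genotypes,
                                     stringsAsFactors = FALSE)),
                 file.path(config$outdir, "cohort.tsv"))
      ab <- data.frame(family = rownames(sim$counts), sim$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
      .write_tsv(ab, file.path(config$outdir, "abundance.tsv"))
      specs <- sim$specs
      specs$alleles <- paste(specs$allele1, specs$allele2, sep = "/")
      .write_tsv(specs[, c("snp_id", "alleles", "maf", "effect_model",
                           "effect_size")],
                 file.path(config$outdir, "snp_specs.tsv"))
    })
  } else {
    run_stage("load", {
      cohort <- utils::read.delim(config$inputs$cohort)
      cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
      out$sim <- list(cohort = cohort,
                      genotypes = read_genotypes_tsv(config$inputs$genotypes),
                      counts = read_abundance_tsv(config$inputs$abundance))
    })
  }
  cohort <- out$sim$cohort
  counts <- out$sim$counts

  if (st["grs"]) {
    run_stage("grs", {
      g <- build_grs(out$sim$genotypes, cohort$bmi, sex = cohort$sex,
                     alpha1 = config$alpha1, merge_alpha = config$merge_alpha,
                     alpha2 = config$alpha2, min_frac = config$min_frac,
                     collinearity_r = config$collinearity_r)
      out$grs <- g
      .write_tsv(g$stage1, file.path(config$outdir, "stage1_screen.tsv"))
      .write_tsv(as.data.frame(g$report),
                 file.path(config$outdir, "selection_report.tsv"))
      if (is.null(g$grs)) stop("no SNP retained; GRS undefined")
      .write_tsv(data.frame(subject_id = names(g$grs), grs = as.integer(g$grs),
                            grs_group = split_by_mean(g$grs)),
                 file.path(config$outdir, "grs.tsv"))
    })
  }

  if (st["diversity"]) {
    run_stage("diversity", {
      div <- diversity_table(counts)
      out$diversity <- div
      assoc <- diversity_association(div$shannon, cohort$bmi, cohort$sex)
      assoc$trait <- "bmi"
      if (!is.null(out$grs)) {
        a2 <- diversity_association(div$shannon, as.numeric(out$grs$grs),
                                    cohort$sex)
        a2$trait <- "grs"
        assoc <- rbind(assoc, a2)
      }
      out$diversity_association <- assoc
      .write_tsv(div, file.path(config$outdir, "diversity.tsv"))
      .write_tsv(assoc, file.path(config$outdir,
                                  "diversity_associations.tsv"))
    })
  }

  if (st["diffabund"]) {
    run_stage("diffabund", {
      filtered <- filter_features(counts)
      relab <- relative_abundance(filtered)
      bmi_group <- bmi_classify(cohort$bmi, binary = TRUE)
      out$lefse <- lda_effect_size(relab, bmi_group,
                                   alpha = config$lefse_alpha,
                                   lda_min = config$lda_min,
                                   n_boot = config$n_boot,
                                   seed = config$seed + 10L)
      out$zig <- zig_fit(filtered, bmi_group,
                         css_quantile = config$css_quantile)
      out$rf <- rf_rank(relab, bmi_group, n_trees = config$rf_trees,
                        n_repeats = config$rf_repeats,
                        train_frac = config$train_frac,
                        seed = config$seed + 11L)
      .write_tsv(out$lefse, file.path(config$outdir, "lefse.tsv"))
      .write_tsv(as.data.frame(out$zig), file.path(config$outdir, "zig.tsv"))
      rf_tab <- out$rf$ranking
      rf_tab$mean_auc <- mean(out$rf$auc)
      .write_tsv(rf_tab, file.path(config$outdir, "rf_ranking.tsv"))
    })
  }

  if (st["interact"]) {
    run_stage("interact", {
      relab_all <- relative_abundance(counts)
      if (!config$family %in% rownames(relab_all)) {
        stop("family '", config$family, "' absent from the abundance matrix")
      }
      fam <- relab_all[config$family, ]
      covar <- cohort[, c("sex", "age", "mets", "energy")]
      grs <- as.numeric(out$grs$grs)
      fits <- lapply(c(all = "all", men = "men", women = "women"),
                     function(s) {
                       interaction_model(cohort$bmi, fam, grs, covar,
                                         stratum = s,
                                         family_name = config$family)
                     })
      out$interaction <- fits
      tab <- do.call(rbind, lapply(names(fits), function(s) {
        f <- fits[[s]]
        cbind(stratum = s, f$coefficients,
              model_p = f$model_p, adj_r_squared = f$adj_r_squared, n = f$n)
      }))
      .write_tsv(tab, file.path(config$outdir, "interaction_models.tsv"))
      curves <- do.call(rbind, lapply(names(fits), function(s) {
        cbind(stratum = s, predict_curve(fits[[s]]))
      }))
      out$curves <- curves
      .write_tsv(curves, file.path(config$outdir, "predicted_curves.tsv"))
    })
  }

  manifest <- list(
    package = "microgrs",
    version = as.character(utils::packageVersion("microgrs")),
    seed = config$seed,
    stages = as.list(config$stages),
    parameters = config[c("alpha1", "merge_alpha", "alpha2", "min_frac",
                          "collinearity_r", "css_quantile", "lefse_alpha",
                          "lda_min", "n_boot", "rf_trees", "rf_repeats",
                          "train_frac", "family")],
    cohort_config = unclass(config$cohort),
    microbiome_config = unclass(config$microbiome)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
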