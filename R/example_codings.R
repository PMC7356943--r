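#' Published ten-SNP risk codings (worked example)
#'
#' The genotype risk codings reported for ten obesity-gene SNPs retained by
#' the three-stage selection in the reference cohort, shipped as a
#' machine-readable table for worked examples and scoring demonstrations.
#' One printed row is internally inconsistent (rs1800592_UCP1 lists the
#' heterozygote on both sides); this table resolves it as the
#' heterozygote-disadvantage coding (non-risk CC+TT, risk CT), the only
#' reading with disjoint categories that keeps the printed risk genotype.
#'
#' @return data frame with `snp_id`, `nonrisk_genotypes`, `risk_genotypes`
#'   (categories joined by "+"), directly usable by [compute_grs()].
#' @export
example_risk_codings <- function() {
  utils::read.delim(system.file("extdata", "example_risk_codings.tsv",
                                package = "microgrs"),
                    stringsAsFactors = FALSE)
}
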