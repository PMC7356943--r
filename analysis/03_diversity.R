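#!/usr/bin/env Rscript
# Step 3: alpha diversity and its sex-stratified trait associations.
#
# Shannon (nats), bias-corrected Chao1 and observed richness per sample,
# then Spearman correlations of Shannon diversity with BMI and with the GRS,
# overall and within each sex. Bray-Curtis dissimilarities are summarized
# (the full matrix is recomputable from the abundance table).

suppressMessages(library(microgrs))

counts <- read_abundance_tsv("results/cohort/abundance.tsv")
cohort <- read.delim("results/cohort/cohort.tsv")
cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
grs <- read.delim("results/grs/grs.tsv")

div <- diversity_table(counts)
assoc_bmi <- diversity_association(div$shannon, cohort$bmi, cohort$sex)
assoc_bmi$trait <- "bmi"
assoc_grs <- diversity_association(div$shannon, grs$grs, cohort$sex)
assoc_grs$trait <- "grs"
assoc <- rbind(assoc_bmi, assoc_grs)

outdir <- "results/diversity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
write.table(div, file.path(outdir, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(assoc, file.path(outdir, "shannon_associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

bc <- bray_curtis(counts)
cat(sprintf("diversity: Shannon %.2f +/- %.2f, Chao1 %.1f +/- %.1f\n",
            mean(div$shannon), sd(div$shannon), mean(div$chao1),
            sd(div$chao1)))
cat(sprintf("Bray-Curtis: median %.2f (IQR %.2f-%.2f) over %d sample pairs\n",
            median(bc[lower.tri(bc)]),
            quantile(bc[lower.tri(bc)], 0.25),
            quantile(bc[lower.tri(bc)], 0.75), sum(lower.tri(bc))))
cat("Spearman associations of Shannon diversity:\n")
print(assoc, digits = 3)
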