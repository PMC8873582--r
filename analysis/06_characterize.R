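#!/usr/bin/env Rscript
# Stage 6: subtype characterization.
#
# Survival curves and log-rank tests over the integrative subtypes,
# concordance with the NMF labelings, categorical copy-number/methylation
# differentials between the best- and worst-prognosis subtypes, the
# three-level (CNV + MET + expression) gene screen with tertile survival
# for its top hit, mutation differentials, and a clinical summary table.

library(momsub)

co <- read_cohort_dir(file.path("results", "cohort"))
dir.create(file.path("results", "characterize"), recursive = TRUE,
           showWarnings = FALSE)
sets <- read.delim(file.path("results", "cor_genes", "cor_gene_sets.tsv"))
ic <- read.delim(file.path("results", "icluster", "icluster_labels.tsv"))
labs <- setNames(ic$subtype, ic$sample_id)[co$survival$sample_id]

lt <- logrank_test(co$survival, labs)
cat(sprintf("overall survival differs across subtypes: chi2 = %.2f (df %d), p = %.3g\n",
            lt$chi2, lt$df, lt$p))
med <- km_median(co$survival, labs)
cat("median survival by subtype (days):\n"); print(round(med))

best <- names(med)[which.max(ifelse(is.na(med), Inf, med))]
worst <- names(med)[which.min(ifelse(is.na(med), Inf, med))]
cat(sprintf("comparing best (%s) vs worst (%s) prognosis subtypes\n", best, worst))
in_two <- labs %in% c(best, worst)

met_gene <- select_representative_probe(co$layers$probes_met, co$layers$exp,
                                        co$manifest, rule = "min_r")
chosen <- attr(met_gene, "chosen_probes")
beta_gene <- co$layers$probes_beta$values[chosen$probe_id, , drop = FALSE]
rownames(beta_gene) <- chosen$gene

cnvcor <- intersect(sets$gene[sets$set == "CNVcor"],
                    rownames(co$layers$cnv$values))
metcor <- intersect(sets$gene[sets$set == "METcor"], rownames(beta_gene))
cnv_cat <- categorize_omics(omics_layer(
  co$layers$cnv$values[cnvcor, in_two, drop = FALSE], "CNV", centered = TRUE))
met_cat <- categorize_omics(omics_layer(
  beta_gene[metcor, in_two, drop = FALSE], "MET"))
genes <- unique(sets$gene)
screen <- three_level_screen(
  omics_layer(co$layers$exp$values[genes, in_two, drop = FALSE], "EXP",
              centered = TRUE),
  cnv_cat, met_cat, labs[in_two], seed = 610)
cat(sprintf("genes different at all three levels (FDR < 0.1): %d\n",
            length(screen$genes)))

if (length(screen$genes)) {
  g <- screen$genes[1]
  ts <- tertile_survival(co$layers$exp$values[g, ], co$survival)
  cat(sprintf("tertile survival for %s: L1/L2/L3 medians %s days, p = %.3g\n",
              g, paste(round(ts$median_survival), collapse = "/"), ts$p))
}

mut <- differential_mutation_test(co$mutations[, in_two, drop = FALSE],
                                  labs[in_two])
cat(sprintf("differentially mutated genes (FDR < 0.1): %s\n",
            paste(mut$gene[mut$q < 0.1], collapse = ", ")))

clin <- clinical_table(labs, co$clinical)
cat("clinical covariates vs subtype (chi-square p):\n"); print(signif(clin$p, 3))

write.table(km_estimator(co$survival, labs),
            file.path("results", "characterize", "km_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(screen$cnv, screen$met, screen$expression),
            file.path("results", "characterize", "three_level_screen.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mut, file.path("results", "characterize", "mutation_differential.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
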