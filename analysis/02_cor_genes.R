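#!/usr/bin/env Rscript
# Stage 2: CNVcor and METcor gene identification.
#
# Correlates each gene's expression with its copy number and (via the
# representative probe) its methylation, characterizes the Fisher-z
# distributions, applies the correlation + survival filters, and summarizes
# the selected sets by chromosome arm and CpG context.

library(momsub)

co <- read_cohort_dir(file.path("results", "cohort"))
dir.create(file.path("results", "cor_genes"), recursive = TRUE, showWarnings = FALSE)
matched <- match_samples(co$layers, co$survival, co$mutations)
layers <- matched$layers

met_gene <- select_representative_probe(layers$probes_met, layers$exp,
                                        co$manifest, rule = "min_r")
chosen <- attr(met_gene, "chosen_probes")
cnv_cor <- correlate_layers(layers$exp, layers$cnv)
met_cor <- correlate_layers(layers$exp, met_gene)

sk_c <- skewness_with_test(cnv_cor$z)
sk_m <- skewness_with_test(met_cor$z)
cat(sprintf("Fisher-z skewness EXP~CNV: %.4f (p = %.3g) — right-skewed, dosage\n",
            sk_c$g1, sk_c$p))
cat(sprintf("Fisher-z skewness EXP~MET: %.4f (p = %.3g) — left-skewed, silencing\n",
            sk_m$g1, sk_m$p))

lr <- logrank_expression_filter(layers$exp, matched$survival)
cnv_cor$p_logrank <- lr$p_logrank[match(cnv_cor$gene, lr$gene)]
met_cor$p_logrank <- lr$p_logrank[match(met_cor$gene, lr$gene)]
sets <- select_cor_genes(cnv_cor, met_cor, alpha_cor = 0.05, alpha_surv = 0.05)
cat(sprintf("CNVcor n = %d, METcor n = %d, overlap = %d\n",
            length(sets$cnvcor), length(sets$metcor), length(sets$overlap)))

ann <- co$annotation
write.table(rbind(cbind(layer = "CNV", cnv_cor), cbind(layer = "MET", met_cor)),
            file.path("results", "cor_genes", "gene_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = c(sets$cnvcor, sets$metcor),
                       set = rep(c("CNVcor", "METcor"),
                                 c(length(sets$cnvcor), length(sets$metcor)))),
            file.path("results", "cor_genes", "cor_gene_sets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(cbind(set = "CNVcor", arm_proportions(sets$cnvcor, ann)),
                  cbind(set = "METcor", arm_proportions(sets$metcor, ann))),
            file.path("results", "cor_genes", "arm_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

bd <- cpg_region_breakdown(sets$metcor, co$manifest, chosen,
                           data.frame(symbol = ann$symbol, coding = ann$coding))
cat("METcor representative probes by CpG region:\n")
print(bd$region_class)
cat("by gene relation:\n")
print(bd$gene_relation)
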