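#!/usr/bin/env Rscript
# Stage 5: directional aberration frequencies and their coupling.
#
# Calls copy-number gains/losses (log2 ratio beyond +/-0.3) and hyper/
# hypomethylation (beta beyond 0.8 / below 0.2), computes per-sample call
# frequencies over all analyzed genes, and correlates the four frequencies
# pairwise across samples — the signature of a shared genomic-instability
# axis is that all six pairs correlate positively.

library(momsub)

co <- read_cohort_dir(file.path("results", "cohort"))
dir.create(file.path("results", "aberrations"), recursive = TRUE,
           showWarnings = FALSE)

met_gene <- select_representative_probe(co$layers$probes_met, co$layers$exp,
                                        co$manifest, rule = "min_r")
chosen <- attr(met_gene, "chosen_probes")
beta_gene <- co$layers$probes_beta$values[chosen$probe_id, , drop = FALSE]
rownames(beta_gene) <- chosen$gene

calls <- call_aberrations(
  cnv = co$layers$cnv,
  met_beta = omics_layer(beta_gene, "MET"))
prof <- frequency_profile(calls)
fc <- pairwise_frequency_correlation(prof)

cat("mean per-sample frequencies:\n")
print(round(colMeans(prof[, -1]), 4))
cat("pairwise frequency correlations across samples:\n")
print(transform(fc[, 1:4], r = round(r, 3), p = signif(p, 3)))

write.table(prof, file.path("results", "aberrations", "frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fc, file.path("results", "aberrations", "frequency_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
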