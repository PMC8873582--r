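# Small synthetic cohorts for fast module tests (fewer genes => fewer
# pattern blocks so the planted design still fits).
small_cohort <- function(seed = 1, n_samples = 60, n_genes = 300, ...) {
  generate_cohort(cohort_config(
    n_samples = n_samples, n_genes = n_genes,
    cnv_blocks_per_pattern = 1, met_blocks_per_pattern = 1,
    seed = seed, ...))
}

# Mid-size cohort used by the scaled-down model-selection checks.
midsize_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(
    n_samples = 150, n_genes = 600,
    cnv_blocks_per_pattern = 2, met_blocks_per_pattern = 1,
    seed = seed, ...))
}

# Correlation-only CNVcor/METcor selection against a cohort.
select_sets <- function(sim, alpha = 0.05) {
  cc <- correlate_layers(sim$cohort$layers$exp, sim$cohort$layers$cnv)
  mc <- correlate_layers(sim$cohort$layers$exp, sim$cohort$layers$met)
  list(cc = cc, mc = mc,
       sets = select_cor_genes(cc, mc, alpha_cor = alpha, alpha_surv = NULL))
}
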