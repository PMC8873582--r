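test_that("the generator is deterministic in its seed", {
  a <- small_cohort(seed = 3)
  b <- small_cohort(seed = 3)
  expect_identical(a$cohort$layers$exp$values, b$cohort$layers$exp$values)
  expect_identical(a$cohort$mutations, b$cohort$mutations)
  expect_identical(a$cohort$survival, b$cohort$survival)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- small_cohort(seed = 4)
  expect_false(identical(a$cohort$layers$exp$values, c$cohort$layers$exp$values))
})

test_that("the noise-free limit collapses subtypes to identical columns", {
  sim <- small_cohort(seed = 5, sigma_cnv = 0, sigma_met = 0, sigma_exp = 0,
                      probe_noise_sd = 0, sigma_inst = 0,
                      dosage_fraction = 0, silenced_fraction = 0)
  cnv <- sim$cohort$layers$cnv$values
  labs <- sim$truth$labels
  for (k in unique(labs)) {
    cols <- cnv[, labs == k, drop = FALSE]
    expect_equal(max(abs(cols - cols[, 1])), 0)
  }
  # without dosage/silencing and zero noise, expression is exactly flat
  expect_equal(max(abs(sim$cohort$layers$exp$values)), 0)
})

test_that("beta values, survival times and basic invariants hold", {
  sim <- small_cohort(seed = 6)
  beta <- sim$cohort$layers$met_beta$values
  expect_true(all(beta > 0 & beta < 1))
  expect_true(all(sim$cohort$survival$time > 0))
  expect_true(all(sim$cohort$mutations %in% 0:1))
  expect_length(intersect(sim$truth$dosage_genes, sim$truth$silenced_genes), 0)
})

test_that("dosage correlation follows the attenuation formula", {
  sim <- generate_cohort(cohort_config(
    n_samples = 300, n_genes = 400,
    cnv_blocks_per_pattern = 1, met_blocks_per_pattern = 1,
    dosage_slope = 1, sigma_exp = 0.05, sigma_cnv = 0.2, seed = 8))
  co <- sim$cohort
  cc <- correlate_layers(co$layers$exp, co$layers$cnv)
  # unshifted dosage genes: pure attenuation r = a sigma_c / sqrt(a^2 s^2 + s_e^2)
  shifted <- sim$truth$mu_cnv[, 1] != 0 | sim$truth$mu_cnv[, 2] != 0 |
    sim$truth$mu_cnv[, 3] != 0
  genes <- intersect(sim$truth$dosage_genes,
                     rownames(co$layers$cnv$values)[!shifted])
  r_obs <- cc$r[match(genes, cc$gene)]
  expect_gt(mean(r_obs), 0.9)   # small sigma_exp: near-deterministic dosage
  expect_equal(mean(r_obs), expected_dosage_r(1, 0.2, 0.05), tolerance = 0.02)
})

test_that("written cohorts round-trip through the readers", {
  sim <- small_cohort(seed = 9, n_samples = 12, n_genes = 200, block_size = 10)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  exp2 <- read_layer(paths["exp"], "EXP", centered = TRUE)
  expect_equal(exp2$values, sim$cohort$layers$exp$values, tolerance = 1e-12)
  pb <- read_layer(paths["probes_beta"], "MET", scale = "beta")
  expect_equal(pb$values, sim$cohort$layers$probes_beta$values,
               tolerance = 1e-12)
  # SEG reconstruction re-mapped to genes reproduces the CNV matrix
  seg <- read_seg(paths["seg"])
  cnv2 <- map_segments_to_genes(seg, sim$cohort$annotation)
  expect_equal(cnv2$values[, colnames(sim$cohort$layers$cnv$values)],
               sim$cohort$layers$cnv$values, tolerance = 1e-12)
  # truth tables list the planted sets
  tg <- read.delim(paths["truth_genes"])
  expect_setequal(tg$gene[tg$dosage == 1], sim$truth$dosage_genes)
  expect_setequal(tg$gene[tg$silenced == 1], sim$truth$silenced_genes)
})
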