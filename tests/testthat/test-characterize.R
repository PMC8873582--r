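test_that("KM estimator matches hand-computed product limits", {
  surv <- data.frame(time = 1:4, event = 1)
  km <- km_estimator(surv, rep("all", 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  km2 <- km_estimator(data.frame(time = 1:4, event = 0), rep("all", 4))
  expect_true(all(km2$surv == 1))
  # mixed 6-record case vs the hand product of (1 - d/n)
  surv3 <- data.frame(time = c(2, 3, 3, 5, 8, 9),
                      event = c(1, 1, 0, 1, 0, 1))
  km3 <- km_estimator(surv3, rep("g", 6))
  ev <- km3[km3$n_event > 0, ]
  expect_equal(ev$surv,
               cumprod(1 - ev$n_event / ev$n_risk))
  expect_equal(ev$surv[1], 1 - 1 / 6)
})

test_that("log-rank test matches the hypergeometric oracle", {
  set.seed(61)
  time <- c(1, 2, 4, 4.5, 6, 9)
  event <- c(1, 0, 1, 1, 1, 0)
  grp <- c(1, 1, 2, 1, 2, 2)
  res <- logrank_test(data.frame(time = time, event = event), grp)
  orc <- logrank_oracle(time, event, grp)
  expect_equal(res$chi2, orc$chi2, tolerance = 1e-10)
  expect_equal(res$df, 1)
  # identical groups: statistic 0, p = 1
  surv <- data.frame(time = rep(c(3, 5, 7), 2), event = rep(c(1, 1, 0), 2))
  same <- logrank_test(surv, rep(1:2, each = 3))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-8)
  expect_error(logrank_test(surv, rep(1, 6)), ">= 2 groups")
})

test_that("concordance combines contingency, chi-square and ARI", {
  a <- rep(1:2, each = 20)
  expect_equal(concordance(a, a)$ari, 1)
  res <- concordance(a, ifelse(a == 1, "x", "y"))
  expect_equal(unname(res$chi2), 40)     # n (ad-bc)^2 / (r1 r2 c1 c2), no correction
  expect_lt(res$p, 1e-5)
  set.seed(62)
  b <- sample(rep(1:3, each = 100))
  shuffled <- concordance(rep(1:3, each = 100), b)
  expect_lt(abs(shuffled$ari), 0.05)
  degen <- concordance(rep(1, 40), a)
  expect_true(is.na(degen$chi2))
  expect_equal(degen$ari, 0)
})

test_that("omics categorization partitions every cell", {
  cnv <- omics_layer(matrix(c(0.5, -0.5, 0, 0.31), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                     "CNV", centered = TRUE)
  cats <- categorize_omics(cnv)
  expect_equal(cats["g1", "s1"], "Gain")
  expect_equal(cats["g2", "s1"], "Loss")
  expect_equal(cats["g1", "s2"], "Normal")
  expect_equal(cats["g2", "s2"], "Gain")
  beta <- omics_layer(matrix(c(0.1, 0.85, 0.5, 0.2), 2, 2,
                             dimnames = dimnames(cnv$values)), "MET")
  mcats <- categorize_omics(beta)
  expect_equal(unname(as.vector(mcats)),
               c("HypoMethy", "HyperMethy", "Normal", "Normal"))
  expect_equal(sum(table(mcats)), length(mcats))  # categories partition
})

test_that("categorical differential test reduces to Fisher on collapsed tables", {
  labels <- rep(c("iC1", "iC2"), each = 4)
  cats <- matrix(c(rep("Gain", 3), "Normal", "Gain", rep("Normal", 3)),
                 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  res <- differential_category_test(cats, labels)
  expect_equal(res$p, 0.4857143, tolerance = 1e-6)   # [[3,1],[1,3]] two-sided
  expect_equal(res$direction, "iC1")
  # identical category distributions: p = 1
  cats2 <- matrix(rep(c("Gain", "Normal"), 4), 1, 8,
                  dimnames = dimnames(cats))
  expect_equal(differential_category_test(cats2, labels)$p, 1)
})

test_that("mutation differential test equals full enumeration", {
  labels <- rep(c("A", "B"), c(12, 18))
  mut <- matrix(0L, 2, 30, dimnames = list(c("gX", "gNever"),
                                           paste0("s", 1:30)))
  mut["gX", 1:10] <- 1L          # 10/12 mutated in A
  mut["gX", 13:15] <- 1L         # 3/18 mutated in B
  expect_message(res <- differential_mutation_test(mut, labels), "skipped")
  expect_equal(nrow(res), 1)
  expect_equal(res$p, fisher_2x2_oracle(10, 2, 3, 15), tolerance = 1e-12)
  expect_equal(res$direction, "A")
  # balanced rates: p = 1
  mut2 <- matrix(rep(c(1L, 0L), 15), 1, 30, dimnames = list("g", paste0("s", 1:30)))
  expect_equal(differential_mutation_test(mut2, labels)$p,
               fisher_2x2_oracle(6, 6, 9, 9), tolerance = 1e-12)
})

test_that("BH adjustment is monotone and equals p on flat inputs", {
  labels <- rep(c("A", "B"), each = 10)
  set.seed(63)
  mut <- matrix(rbinom(200, 1, 0.3), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  mut[, 1] <- 1L  # keep every gene mutated somewhere
  res <- differential_mutation_test(mut, labels)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("tertile survival splits 3/3/3 and degrades gracefully", {
  surv <- data.frame(time = c(5, 8, 13, 21, 34, 3, 2, 44, 60),
                     event = c(1, 1, 0, 1, 1, 1, 0, 1, 1))
  res <- tertile_survival(1:9, surv)
  expect_equal(unname(as.vector(res$group_sizes)), c(3, 3, 3))
  expect_false(res$fallback)
  const <- tertile_survival(rep(2, 9), surv)
  expect_true(const$fallback)
  expect_true(const$degenerate)
  expect_equal(const$p, 1)
})

test_that("clinical tables conserve counts and detect label-linked covariates", {
  sim <- small_cohort(seed = 64, n_samples = 150)
  labs <- sim$truth$labels
  ct <- clinical_table(labs, sim$cohort$clinical)
  expect_equal(sum(ct$tables$stage), 150)
  expect_equal(sum(ct$tables$grade), 150)
  expect_lt(ct$p[["stage"]], 0.05)   # stage probabilities depend on subtype
})

test_that("the three-level screen intersects its component tests", {
  sim <- small_cohort(seed = 65, n_samples = 80)
  co <- sim$cohort
  labs <- ifelse(sim$truth$labels == 1, "iC1", "iC2")
  keep <- sim$truth$labels %in% 1:2
  genes <- co$annotation$symbol[1:100]
  expl <- omics_layer(co$layers$exp$values[genes, keep], "EXP", centered = TRUE)
  cnv_cat <- categorize_omics(omics_layer(co$layers$cnv$values[genes, keep],
                                          "CNV", centered = TRUE))
  met_cat <- categorize_omics(omics_layer(co$layers$met_beta$values[genes, keep],
                                          "MET"))
  sc <- three_level_screen(expl, cnv_cat, met_cat, labs[keep])
  expect_true(all(sc$genes %in% sc$cnv$gene[sc$cnv$q < 0.1]))
  expect_true(all(sc$genes %in% sc$met$gene[sc$met$q < 0.1]))
  expect_true(all(sc$genes %in% sc$expression$gene[sc$expression$q < 0.1]))
})
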