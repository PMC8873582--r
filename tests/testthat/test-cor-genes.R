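test_that("correlate_layers agrees with a naive covariance oracle", {
  set.seed(21)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  y <- matrix(rnorm(200), 20, 10, dimnames = dimnames(x))
  res <- correlate_layers(omics_layer(x, "EXP"), omics_layer(y, "CNV"))
  expect_equal(res$r, naive_row_cor(x, y), tolerance = 1e-12)
  # p-values match cor.test
  ct <- cor.test(x[1, ], y[1, ])
  expect_equal(res$p_cor[1], ct$p.value, tolerance = 1e-10)
})

test_that("perfect and degenerate correlations are handled", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  y <- -x
  y[3, ] <- x[3, ]       # r = +1
  y[4, ] <- 0            # zero variance -> excluded
  res <- correlate_layers(omics_layer(x, "EXP"), omics_layer(y, "CNV"))
  expect_equal(res$r[res$gene == "g1"], -1)
  expect_true(is.finite(res$z[res$gene == "g1"]))   # clamped before atanh
  expect_equal(res$r[res$gene == "g3"], 1)
  expect_false("g4" %in% res$gene)
  expect_equal(attr(res, "excluded"), "g4")
})

test_that("fisher_z is the inverse hyperbolic tangent", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)  # 0.5 * log(3)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("skewness statistic and D'Agostino test behave canonically", {
  expect_equal(skewness_with_test(c(1, 2, 3))$g1, 0)
  set.seed(22)
  x <- rexp(10000)
  sk <- skewness_with_test(x)
  expect_equal(sk$g1, 2, tolerance = 0.1)      # exponential population skew
  expect_lt(sk$p, 1e-5)
  mirrored <- skewness_with_test(-x)
  expect_equal(mirrored$g1, -sk$g1, tolerance = 1e-12)
  # symmetric normal data: no evidence of skew
  expect_gt(skewness_with_test(qnorm(ppoints(500)))$p, 0.9)
  expect_error(skewness_with_test(rep(1, 10)), "constant")
})

test_that("median-split log-rank filter flags degenerate genes", {
  set.seed(23)
  n <- 40
  surv <- data.frame(sample_id = paste0("s", 1:n),
                     time = rexp(n, 0.01), event = rbinom(n, 1, 0.7))
  m <- rbind(flat = rep(1, n), noisy = rnorm(n))
  colnames(m) <- surv$sample_id
  res <- logrank_expression_filter(omics_layer(m, "EXP"), surv)
  expect_true(res$degenerate[res$gene == "flat"])
  expect_equal(res$p_logrank[res$gene == "flat"], 1)
  expect_false(res$degenerate[res$gene == "noisy"])
  expect_true(res$p_logrank[res$gene == "noisy"] <= 1)
})

test_that("cor-gene selection applies sign, alpha and survival rules", {
  tab <- function(...) data.frame(..., stringsAsFactors = FALSE)
  cnv <- tab(gene = c("a", "b", "c"), r = c(0.6, -0.5, 0.4),
             z = atanh(c(0.6, -0.5, 0.4)),
             p_cor = c(0.001, 1e-6, 0.2), p_logrank = c(0.01, 0.001, 0.01))
  met <- tab(gene = c("a", "b", "c"), r = c(-0.6, 0.5, -0.3),
             z = atanh(c(-0.6, 0.5, -0.3)),
             p_cor = c(0.001, 1e-6, 0.01), p_logrank = c(0.01, 0.001, 0.2))
  sets <- select_cor_genes(cnv, met)
  expect_equal(sets$cnvcor, "a")   # b: wrong sign despite tiny p; c: weak p
  expect_equal(sets$metcor, "a")   # c fails the survival filter
  expect_equal(sets$overlap, "a")
  # without the survival filter c re-enters metcor
  expect_setequal(select_cor_genes(cnv, met, alpha_surv = NULL)$metcor,
                  c("a", "c"))
})

test_that("selection is monotone in both alpha thresholds", {
  set.seed(24)
  n <- 200
  tab <- data.frame(gene = paste0("g", 1:n), r = runif(n, -1, 1),
                    p_cor = runif(n), p_logrank = runif(n))
  tab$z <- atanh(tab$r * 0.999)
  alphas <- c(0.01, 0.05, 0.2, 0.8)
  prev_c <- character(0); prev_m <- character(0)
  for (a in alphas) {
    s <- select_cor_genes(tab, tab, alpha_cor = a, alpha_surv = a)
    expect_true(all(prev_c %in% s$cnvcor))
    expect_true(all(prev_m %in% s$metcor))
    prev_c <- s$cnvcor; prev_m <- s$metcor
  }
})

test_that("arm proportions count selected genes per arm", {
  ann <- data.frame(symbol = paste0("g", 1:20),
                    chromosome = rep(c("17", "5"), each = 10),
                    arm = rep(c("p", "q"), 10))
  # 17p holds genes g1,g3,...: select 3 of its analyzed genes
  p17 <- ann$symbol[ann$chromosome == "17" & ann$arm == "p"]
  res <- arm_proportions(p17[1:3], ann)
  expect_equal(res$fraction[res$chromosome == "17" & res$arm == "p"],
               3 / length(p17))
  expect_equal(sum(arm_proportions(character(0), ann)$fraction), 0)
  all_in <- arm_proportions(ann$symbol, ann)
  expect_true(all(all_in$fraction == 1))
})

test_that("CpG breakdown tallies representative probes", {
  manifest <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbol = c("g1", "g2", "g3", "g4"),
    region_class = c("Island", "Island", "Shore", "OpenSea"),
    gene_relation = c("Promoter", "Body", "Promoter", "Other"))
  chosen <- data.frame(gene = paste0("g", 1:4), probe_id = paste0("p", 1:4))
  ann <- data.frame(symbol = paste0("g", 1:4),
                    coding = c(TRUE, TRUE, FALSE, TRUE))
  bd <- cpg_region_breakdown(c("g1", "g2", "g3"), manifest, chosen, ann)
  expect_equal(sum(bd$region_class), 3)          # conservation
  expect_equal(unname(bd$region_class[["Island"]]), 2)
  expect_equal(unname(bd$gene_relation[["Promoter"]]), 2)
  expect_equal(unname(bd$coding[["non-coding"]]), 1)
})

test_that("planted dosage and silencing skew the z distributions", {
  res <- select_sets(small_cohort(seed = 25, n_samples = 120))
  expect_gt(skewness_with_test(res$cc$z)$g1, 0)
  expect_lt(skewness_with_test(res$mc$z)$g1, 0)
})
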