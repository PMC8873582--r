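test_that("read_layer parses TSV matrices and preserves missingness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "g1\t1.5\t2", "g2\tNA\t-0.25", "g3\t0\t7"), f)
  lay <- read_layer(f, "EXP")
  expect_equal(dim(lay), c(3L, 2L))
  expect_equal(lay$values["g1", "S2"], 2)
  expect_true(is.na(lay$values["g2", "S1"]))
  expect_equal(sum(is.na(lay$values)), 1L)

  writeLines(c("gene\tS1\tS1", "g1\t1\t2"), f)
  expect_error(read_layer(f, "EXP"), "duplicate sample")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_layer(f, "EXP"), "duplicate feature")
  writeLines(c("gene\tS1\tS2", "g1\t1\tx", "g2\t3\t4"), f)
  expect_error(read_layer(f, "EXP"), "non-numeric.*g1.*S2")
})

test_that("omics_layer enforces beta-range and id invariants", {
  m <- matrix(c(0.1, 0.9), 1, 2, dimnames = list("g", c("a", "b")))
  expect_s3_class(omics_layer(m, "MET"), "omics_layer")
  m2 <- m; m2[1] <- 1.2
  expect_error(omics_layer(m2, "MET"), "\\[0, 1\\]")
  expect_silent(omics_layer(m2, "MET", scale = "M", centered = TRUE))
})

test_that("filter_features uses a strict 'over threshold' rule", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m[1, 1:4] <- NA  # 40% missing
  m[2, 1:3] <- NA  # exactly 30%
  lay <- omics_layer(m, "EXP")
  kept <- filter_features(lay, max_missing_fraction = 0.3)
  expect_setequal(rownames(kept$values), c("g2", "g3", "g4"))
  # threshold 1 with the flag off is the identity
  expect_identical(filter_features(lay, max_missing_fraction = 1)$values, m)
  # sex chromosomes dropped only on request
  ann <- data.frame(feature_id = paste0("g", 1:4),
                    chromosome = c("1", "X", "2", "22"))
  kept2 <- filter_features(lay, ann, max_missing_fraction = 1,
                           drop_sex_chromosomes = TRUE)
  expect_setequal(rownames(kept2$values), c("g1", "g3", "g4"))
  m3 <- m; m3[3, 1] <- NA; m3[4, 1] <- NA  # now every feature has a gap
  expect_error(filter_features(omics_layer(m3, "EXP"), max_missing_fraction = 0),
               "all features removed")
})

test_that("knn_impute matches a brute-force neighbor-mean oracle", {
  set.seed(42)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m[2, 3] <- NA
  m[5, 1] <- NA
  lay <- omics_layer(m, "EXP")
  out <- knn_impute(lay, k = 2)$values
  # oracle: rank complete features by mean squared difference on shared cells
  impute_oracle <- function(m, i, s, k) {
    d <- sapply(seq_len(nrow(m)), function(j) {
      if (j == i) return(Inf)
      joint <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(joint) || is.na(m[j, s])) return(Inf)
      mean((m[i, joint] - m[j, joint])^2)
    })
    mean(m[order(d)[seq_len(k)], s])
  }
  expect_equal(out[2, 3], impute_oracle(m, 2, 3, 2), tolerance = 1e-12)
  expect_equal(out[5, 1], impute_oracle(m, 5, 1, 2), tolerance = 1e-12)
  expect_false(anyNA(out))
})

test_that("knn_impute is idempotent and falls back gracefully", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  lay <- omics_layer(m, "EXP")
  expect_identical(knn_impute(lay, k = 2)$values, m)
  m[1, 2] <- NA
  expect_warning(out <- knn_impute(omics_layer(m, "EXP"), k = 10),
                 "fallback")
  expect_equal(out$values[1, 2], mean(m[1, ], na.rm = TRUE))
})

test_that("k=1 imputation copies the nearest neighbor's value", {
  m <- rbind(g1 = c(1, 2, NA, 4),
             g2 = c(1, 2, 3, 4),      # identical elsewhere -> nearest
             g3 = c(9, -4, 7, 0))
  colnames(m) <- paste0("s", 1:4)
  out <- knn_impute(omics_layer(m, "EXP"), k = 1)
  expect_equal(out$values["g1", "s3"], 3)
})

test_that("segment-to-gene mapping is a length-weighted mean", {
  ann <- data.frame(symbol = c("gA", "gB", "gC"), chromosome = "1",
                    start = c(100L, 1000L, 5000L), end = c(199L, 1399L, 5999L))
  segs <- data.frame(
    sample_id = "S1", chromosome = "1",
    start = c(1L, 1000L, 1300L),
    end = c(500L, 1299L, 1399L),
    segment_mean = c(0.7, 0.2, 0.6))
  lay <- map_segments_to_genes(segs, ann)
  expect_equal(lay$values["gA", "S1"], 0.7)                        # fully inside
  expect_equal(lay$values["gB", "S1"], (0.2 * 300 + 0.6 * 100) / 400)
  expect_true(is.na(lay$values["gC", "S1"]))                       # no overlap
  # symmetric +/- overlap cancels
  segs2 <- data.frame(sample_id = "S1", chromosome = "1",
                      start = c(100L, 150L), end = c(149L, 199L),
                      segment_mean = c(0.5, -0.5))
  expect_equal(map_segments_to_genes(segs2, ann)$values["gA", "S1"], 0)
})

test_that("segment mapping is invariant to splitting segments", {
  set.seed(7)
  ann <- data.frame(symbol = paste0("g", 1:6), chromosome = "2",
                    start = seq(100L, by = 1000L, length.out = 6),
                    end = seq(100L, by = 1000L, length.out = 6) + 799L)
  segs <- data.frame(sample_id = "S1", chromosome = "2",
                     start = c(1L, 2500L), end = c(2499L, 7000L),
                     segment_mean = c(0.4, -0.9))
  split_at <- function(seg, pos) {
    rbind(transform(seg, end = pos), transform(seg, start = pos + 1L))
  }
  segs_split <- rbind(split_at(segs[1, ], 1200L), split_at(segs[2, ], 5100L))
  expect_equal(map_segments_to_genes(segs, ann)$values,
               map_segments_to_genes(segs_split, ann)$values)
})

test_that("representative probe selection honors min_r and mean_r rules", {
  set.seed(11)
  n <- 40
  e <- rnorm(n)
  mk <- function(rho) rho * e + sqrt(1 - rho^2) * rnorm(n)
  pv <- rbind(p1 = mk(-0.7), p2 = mk(-0.2), p3 = mk(0.3), q1 = mk(0.5))
  colnames(pv) <- paste0("s", 1:n)
  ev <- rbind(gM = e, gS = rnorm(n))
  colnames(ev) <- colnames(pv)
  manifest <- data.frame(probe_id = c("p1", "p2", "p3", "q1"),
                         gene_symbol = c("gM", "gM", "gM", "gS"))
  probe_lay <- omics_layer(pv, "MET", centered = TRUE, scale = "M")
  exp_lay <- omics_layer(ev, "EXP", centered = TRUE)

  gm_r <- sapply(c("p1", "p2", "p3"), function(p) cor(pv[p, ], e))
  out_min <- select_representative_probe(probe_lay, exp_lay, manifest, "min_r")
  ch <- attr(out_min, "chosen_probes")
  expect_equal(ch$probe_id[ch$gene == "gM"], names(which.min(gm_r)))
  expect_equal(ch$probe_id[ch$gene == "gS"], "q1")   # single probe: identity
  expect_equal(out_min$values["gS", ], pv["q1", ])

  out_mean <- select_representative_probe(probe_lay, exp_lay, manifest, "mean_r")
  ch2 <- attr(out_mean, "chosen_probes")
  expect_equal(ch2$probe_id[ch2$gene == "gM"],
               names(which.min(abs(gm_r - mean(gm_r)))))
})

test_that("match_samples intersects and orders consistently", {
  mk <- function(ids) omics_layer(
    matrix(seq_along(ids), 1, length(ids),
           dimnames = list("g1", ids)), "EXP")
  out <- match_samples(list(a = mk(c("A", "B", "C", "E")),
                            b = mk(c("B", "C", "D", "E"))))
  expect_equal(out$sample_ids, c("B", "C", "E"))
  expect_equal(colnames(out$layers$a$values), out$sample_ids)
  expect_error(match_samples(list(a = mk(c("A", "B")), b = mk(c("B", "C")))),
               "fewer than 3")
  # identical id sets: unchanged content
  same <- match_samples(list(a = mk(c("A", "B", "C")), b = mk(c("A", "B", "C"))))
  expect_equal(same$layers$a$values[1, ], c(A = 1, B = 2, C = 3))
})

test_that("mutation matrix keeps only missense and nonsense records", {
  maf <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                    gene_symbol = c("TP53", "TTN", "TP53", "TP53"),
                    variant_class = c("missense", "synonymous",
                                      "nonsense", "silent"))
  mm <- mutation_matrix(maf, samples = c("s1", "s2", "s3"))
  expect_equal(sort(rownames(mm)), "TP53")
  expect_equal(unname(mm["TP53", ]), c(1L, 1L, 0L))
})

test_that("read_seg supports both coordinate dialects", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tSegment_Mean",
               "S1\t1\t0\t100\t0.5"), f)
  one <- read_seg(f, "zero_half_open")
  expect_equal(one$start, 1L)
  expect_equal(one$end, 100L)
})
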