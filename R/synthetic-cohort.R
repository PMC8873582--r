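#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defaults emulate a ~300-sample stomach-adenocarcinoma-like cohort with
#' three latent molecular subtypes: regional copy-number shifts with a
#' positive dosage effect on expression, beta-valued methylation with a
#' negative (silencing) effect planted on the M-value scale, subtype-specific
#' exponential survival hazards (worst/best hazard ratio 2.5), per-subtype
#' mutation rates on a small gene panel, and a per-sample genomic-instability
#' factor that couples copy-number and methylation aberration frequencies.
#'
#' Copy-number and methylation subtype structure is planted on contiguous
#' 25-gene blocks. Each aberrant block carries one of the six sign patterns
#' over the three subtypes (permutations of (+shift, 0, -shift)), each
#' pattern used equally often, so every subtype carries exactly the same
#' number of gain and loss (hyper and hypo) blocks. This balance makes the
#' per-sample aberration frequencies independent of subtype in expectation,
#' which isolates the instability factor as the only source of
#' frequency coupling.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param k_subtypes Number of planted subtypes (patterns assume 3).
#' @param mixing Subtype mixing proportions (sums to 1).
#' @param block_size Genes per aberration block.
#' @param cnv_blocks_per_pattern,met_blocks_per_pattern Blocks per sign
#'   pattern and layer (6 patterns each).
#' @param cnv_shift Magnitude of subtype copy-number block shifts (log2 units).
#' @param met_shift Magnitude of subtype methylation block shifts (M units).
#' @param sigma_cnv,sigma_met,sigma_exp Per-layer noise standard deviations.
#' @param met_baseline_sd SD of per-gene baseline M-values (centered at 0).
#' @param dosage_fraction,dosage_slope Fraction of genes with a positive
#'   copy-number dosage effect on expression and its slope `a`.
#' @param silenced_fraction,silencing_slope Fraction of genes silenced by
#'   methylation and the (positive) slope `b` applied as `-b * M`.
#' @param overlap_fraction Fraction of the silenced set allowed to overlap the
#'   dosage set (0 = disjoint).
#' @param exp_shift_sd SD of optional direct subtype mean shifts on
#'   expression (0 = all subtype signal reaches expression through CNV/MET).
#' @param sigma_inst Scale of the half-normal per-sample instability factor.
#' @param hazards Per-subtype exponential death rates (per day).
#' @param censor_horizon Upper end (days) of the uniform censoring time.
#' @param n_panel,panel_high_rate,panel_base_rate,panel_high_genes Mutation
#'   panel size, elevated rate, background rate and number of genes elevated
#'   in subtype 1.
#' @param second_probe_fraction Fraction of genes carrying a second probe.
#' @param probe_noise_sd Probe-level noise around the gene M-value.
#' @param seed Integer seed; the whole cohort derives from one seeded generator.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300, n_genes = 2000, k_subtypes = 3,
                          mixing = rep(1 / 3, 3), block_size = 25,
                          cnv_blocks_per_pattern = 5, met_blocks_per_pattern = 4,
                          cnv_shift = 0.45, met_shift = 1.2,
                          sigma_cnv = 0.2, sigma_met = 0.6, sigma_exp = 1.0,
                          met_baseline_sd = 1.8,
                          dosage_fraction = 0.15, dosage_slope = 3.75,
                          silenced_fraction = 0.15, silencing_slope = 0.8,
                          overlap_fraction = 0, exp_shift_sd = 0,
                          sigma_inst = 0.8,
                          hazards = c(1 / 1500, 1 / 950, 1 / 600),
                          censor_horizon = 4000,
                          n_panel = 30, panel_high_rate = 0.4,
                          panel_base_rate = 0.05, panel_high_genes = 10,
                          second_probe_fraction = 0.3, probe_noise_sd = 0.3,
                          seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 3, cfg$n_genes >= cfg$block_size,
            cfg$k_subtypes == length(cfg$mixing),
            abs(sum(cfg$mixing) - 1) < 1e-8,
            cfg$dosage_fraction >= 0, cfg$dosage_fraction <= 1,
            cfg$silenced_fraction >= 0, cfg$silenced_fraction <= 1,
            cfg$dosage_slope >= 0, cfg$silencing_slope >= 0,
            cfg$sigma_inst >= 0, all(cfg$hazards > 0),
            length(cfg$hazards) == cfg$k_subtypes)
  class(cfg) <- "cohort_config"
  cfg
}

#' Expected dosage correlation under attenuation
#'
#' Closed-form Pearson correlation between expression and copy number for a
#' dosage gene: `r = a * sigma_c / sqrt(a^2 sigma_c^2 + sigma_e^2)`.
#'
#' @param a Dosage slope.
#' @param sigma_c SD of the gene's copy-number values across samples.
#' @param sigma_e Expression noise SD.
#' @export
expected_dosage_r <- function(a, sigma_c, sigma_e) {
  a * sigma_c / sqrt(a^2 * sigma_c^2 + sigma_e^2)
}

# six sign patterns over three subtypes: permutations of (+1, 0, -1)
subtype_sign_patterns <- function() {
  rbind(c(1, 0, -1), c(1, -1, 0), c(0, 1, -1),
        c(-1, 0, 1), c(-1, 1, 0), c(0, -1, 1))
}

gene_annotation_table <- function(n_genes) {
  per_chr <- diff(round(seq(0, n_genes, length.out = 23)))
  chrom <- rep(1:22, per_chr)
  idx_in_chr <- unlist(lapply(per_chr, seq_len), use.names = FALSE)
  arm <- unlist(lapply(per_chr, function(m)
    rep(c("p", "q"), c(floor(m / 2), ceiling(m / 2)))), use.names = FALSE)
  start <- (idx_in_chr - 1L) * 100000L + 1L
  data.frame(symbol = sprintf("G%04d", seq_len(n_genes)),
             feature_id = sprintf("G%04d", seq_len(n_genes)),
             chromosome = as.character(chrom), arm = arm,
             start = start, end = start + 19999L,
             coding = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), length.out = n_genes),
             stringsAsFactors = FALSE)
}

#' Generate a matched synthetic multi-omics cohort with known truth
#'
#' Generative model, in order: (1) subtype labels from the mixing proportions
#' and instability `u_i ~ |N(0, sigma_inst)|`; (2) gene-level copy number
#' `c_ij ~ N(mu_cnv * (1 + u_i), sigma_cnv)` with block/subtype means;
#' (3) methylation M-values `m_ij ~ N(base_j + shift_j * (1 + u_i),
#' sigma_met)` — instability amplifies the planted aberration, not the
#' normal-tissue baseline — and `beta = 2^m / (2^m + 1)`; (4) expression
#' `e_ij = a * c_ij * [dosage] - b * m_ij * [silenced] + N(0, sigma_exp)`
#' (plus optional direct subtype shifts); (5) exponential survival per
#' subtype with uniform censoring; (6) Bernoulli panel mutations.
#'
#' @param config A [cohort_config()].
#' @return List with elements `cohort` (layers, survival, clinical, mutations,
#'   annotation, manifest) and `truth` (labels, planted gene sets, instability,
#'   hazards, mutation rates, per-gene subtype means).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples; p <- cf$n_genes; K <- cf$k_subtypes
  samples <- sprintf("S%03d", seq_len(n))
  ann <- gene_annotation_table(p)
  genes <- ann$symbol

  ## ---- planted structure -------------------------------------------------
  patterns <- subtype_sign_patterns()
  n_blocks <- p %/% cf$block_size
  n_cnv_b <- nrow(patterns) * cf$cnv_blocks_per_pattern
  n_met_b <- nrow(patterns) * cf$met_blocks_per_pattern
  if (n_cnv_b + n_met_b > n_blocks)
    stop("not enough gene blocks for the requested patterns")
  # CNV and MET aberrant regions are disjoint so each planted gene set has a
  # single, well-defined causal layer
  drawn <- sample(n_blocks, n_cnv_b + n_met_b)
  cnv_blocks <- data.frame(block = drawn[seq_len(n_cnv_b)],
                           pattern = rep(seq_len(nrow(patterns)),
                                         each = cf$cnv_blocks_per_pattern))
  met_blocks <- data.frame(block = drawn[n_cnv_b + seq_len(n_met_b)],
                           pattern = rep(seq_len(nrow(patterns)),
                                         each = cf$met_blocks_per_pattern))
  block_of_gene <- rep(seq_len(n_blocks), each = cf$block_size,
                       length.out = p)
  # per-gene x subtype mean shifts
  shift_matrix <- function(blocks, shift) {
    mu <- matrix(0, p, K)
    for (i in seq_len(nrow(blocks))) {
      g <- which(block_of_gene == blocks$block[i])
      mu[g, ] <- mu[g, ] +
        matrix(patterns[blocks$pattern[i], ] * shift, length(g), K, byrow = TRUE)
    }
    mu
  }
  mu_cnv <- shift_matrix(cnv_blocks, cf$cnv_shift)          # p x K
  met_base <- stats::rnorm(p, 0, cf$met_baseline_sd)
  met_shift_mat <- shift_matrix(met_blocks, cf$met_shift)   # aberration part
  mu_met <- met_base + met_shift_mat

  n_dos <- round(cf$dosage_fraction * p)
  n_sil <- round(cf$silenced_fraction * p)
  dosage <- sample(p, n_dos)
  n_over <- round(cf$overlap_fraction * n_sil)
  pool_disjoint <- setdiff(seq_len(p), dosage)
  silenced <- c(sample(dosage, n_over),
                sample(pool_disjoint, n_sil - n_over))
  exp_shift <- if (cf$exp_shift_sd > 0)
    matrix(stats::rnorm(p * K, 0, cf$exp_shift_sd), p, K) else matrix(0, p, K)

  ## ---- sample-level draws ------------------------------------------------
  labels <- sample.int(K, n, replace = TRUE, prob = cf$mixing)
  u <- abs(stats::rnorm(n, 0, cf$sigma_inst))
  scale_u <- matrix(1 + u, p, n, byrow = TRUE)

  # instability scales the aberration component of the mean, not the
  # baseline: a sample's planted shifts get larger with u, while the
  # normal-tissue methylation landscape stays put
  cnv <- mu_cnv[, labels, drop = FALSE] * scale_u +
    matrix(stats::rnorm(p * n, 0, cf$sigma_cnv), p, n)
  mval <- met_base + met_shift_mat[, labels, drop = FALSE] * scale_u +
    matrix(stats::rnorm(p * n, 0, cf$sigma_met), p, n)
  beta <- 2^mval / (2^mval + 1)

  dos_ind <- as.numeric(seq_len(p) %in% dosage)
  sil_ind <- as.numeric(seq_len(p) %in% silenced)
  expm <- exp_shift[, labels, drop = FALSE] +
    cf$dosage_slope * cnv * dos_ind -
    cf$silencing_slope * mval * sil_ind +
    matrix(stats::rnorm(p * n, 0, cf$sigma_exp), p, n)

  dimnames(cnv) <- dimnames(mval) <- dimnames(beta) <- dimnames(expm) <-
    list(genes, samples)

  ## ---- probes ------------------------------------------------------------
  second <- sample(p, round(cf$second_probe_fraction * p))
  probe_gene <- c(seq_len(p), sort(second))
  probe_id <- c(sprintf("P_%s_1", genes),
                sprintf("P_%s_2", genes[sort(second)]))
  probe_m <- mval[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(probe_gene) * n, 0, cf$probe_noise_sd),
           length(probe_gene), n)
  rownames(probe_m) <- probe_id
  probe_beta <- 2^probe_m / (2^probe_m + 1)
  probe_centered <- probe_m - met_base[probe_gene]   # minus normal-tissue mean
  manifest <- data.frame(
    probe_id = probe_id,
    gene_symbol = genes[probe_gene],
    region_class = sample(c("Island", "Shore", "Shelf", "OpenSea"),
                          length(probe_id), replace = TRUE,
                          prob = c(0.45, 0.25, 0.1, 0.2)),
    gene_relation = sample(c("Promoter", "5'UTR", "FirstExon", "Body", "Other"),
                           length(probe_id), replace = TRUE,
                           prob = c(0.4, 0.1, 0.1, 0.3, 0.1)),
    stringsAsFactors = FALSE)

  ## ---- survival, clinical, mutations --------------------------------------
  death <- stats::rexp(n, rate = cf$hazards[labels])
  cens <- stats::runif(n, 0, cf$censor_horizon)
  survival <- data.frame(sample_id = samples,
                         time = pmin(death, cens),
                         event = as.integer(death <= cens),
                         stringsAsFactors = FALSE)
  stage_prob <- rbind(c(0.4, 0.3, 0.2, 0.1),
                      c(0.25, 0.3, 0.25, 0.2),
                      c(0.1, 0.2, 0.3, 0.4))[labels, , drop = FALSE]
  stage <- apply(stage_prob, 1, function(pr)
    sample(c("I", "II", "III", "IV"), 1, prob = pr))
  clinical <- data.frame(sample_id = samples, stage = stage,
                         grade = sample(c("G1", "G2", "G3"), n, replace = TRUE),
                         stringsAsFactors = FALSE)

  panel <- sprintf("MUT%02d", seq_len(cf$n_panel))
  rates <- matrix(cf$panel_base_rate, cf$n_panel, K,
                  dimnames = list(panel, paste0("subtype", seq_len(K))))
  rates[seq_len(min(cf$panel_high_genes, cf$n_panel)), 1] <- cf$panel_high_rate
  mut <- matrix(stats::rbinom(cf$n_panel * n, 1, rates[, labels]),
                cf$n_panel, n, dimnames = list(panel, samples))

  ## ---- package up ----------------------------------------------------------
  layers <- list(
    exp = omics_layer(expm, kind = "EXP", centered = TRUE),
    cnv = omics_layer(cnv, kind = "CNV", centered = TRUE),
    met = omics_layer(mval - met_base, kind = "MET", centered = TRUE, scale = "M"),
    met_beta = omics_layer(beta, kind = "MET", centered = FALSE, scale = "beta"),
    probes_met = omics_layer(probe_centered, kind = "MET", centered = TRUE,
                             scale = "M"),
    probes_beta = omics_layer(probe_beta, kind = "MET", centered = FALSE,
                              scale = "beta"))

  best <- which.min(cf$hazards); worst <- which.max(cf$hazards)
  opposite <- function(mu) mu[, best] * mu[, worst] < 0   # opposite nonzero shifts
  survival_linked <- union(
    intersect(dosage, which(opposite(mu_cnv))),
    intersect(silenced, which(opposite(mu_met - met_base))))

  truth <- list(labels = stats::setNames(labels, samples),
                instability = stats::setNames(u, samples),
                dosage_genes = genes[sort(dosage)],
                silenced_genes = genes[sort(silenced)],
                survival_linked_genes = genes[sort(survival_linked)],
                mu_cnv = mu_cnv, mu_met = mu_met, met_base = met_base,
                cnv_blocks = cnv_blocks, met_blocks = met_blocks,
                block_of_gene = block_of_gene,
                hazard = stats::setNames(cf$hazards[labels], samples),
                mutation_rates = rates,
                config = cf)

  list(cohort = list(layers = layers, survival = survival, clinical = clinical,
                     mutations = mut, annotation = ann, manifest = manifest,
                     sample_ids = samples),
       truth = truth)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits matrix TSVs, a SEG file reconstructed from the gene-level copy
#' numbers (one segment per gene and sample, spanning the gene body), the
#' probe manifest, gene annotation, clinical survival TSV, MAF-lite mutation
#' records and flat truth tables. Reading the files back reproduces the
#' matrices exactly.
#'
#' @param sim Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort; tr <- sim$truth
  paths <- c(
    exp = file.path(dir, "exp.tsv"),
    cnv_genes = file.path(dir, "cnv_genes.tsv"),
    seg = file.path(dir, "cnv.seg"),
    probes_beta = file.path(dir, "met_probes_beta.tsv"),
    probes_met = file.path(dir, "met_probes_centered.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    genes = file.path(dir, "genes.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    maf = file.path(dir, "mutations_maf.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"))
  write_matrix_tsv(co$layers$exp, paths["exp"], id_col = "gene")
  write_matrix_tsv(co$layers$cnv, paths["cnv_genes"], id_col = "gene")
  write_matrix_tsv(co$layers$probes_beta, paths["probes_beta"], id_col = "probe_id")
  write_matrix_tsv(co$layers$probes_met, paths["probes_met"], id_col = "probe_id")

  ann <- co$annotation
  cnv <- co$layers$cnv$values
  seg <- data.table::data.table(
    Sample = rep(colnames(cnv), each = nrow(cnv)),
    Chromosome = rep(ann$chromosome, ncol(cnv)),
    Start = rep(ann$start, ncol(cnv)),
    End = rep(ann$end, ncol(cnv)),
    Segment_Mean = as.vector(cnv))
  data.table::fwrite(seg, paths["seg"], sep = "\t", quote = FALSE)

  data.table::fwrite(co$manifest, paths["manifest"], sep = "\t", quote = FALSE)
  data.table::fwrite(ann, paths["genes"], sep = "\t", quote = FALSE)
  clin <- merge(co$survival, co$clinical, by = "sample_id", sort = TRUE)
  names(clin)[names(clin) == "time"] <- "os_days"
  names(clin)[names(clin) == "event"] <- "os_event"
  data.table::fwrite(clin, paths["clinical"], sep = "\t", quote = FALSE)

  idx <- which(co$mutations == 1L, arr.ind = TRUE)
  maf <- data.table::data.table(
    sample_id = colnames(co$mutations)[idx[, 2]],
    gene_symbol = rownames(co$mutations)[idx[, 1]],
    variant_class = "missense")
  data.table::setorder(maf, sample_id, gene_symbol)
  data.table::fwrite(maf, paths["maf"], sep = "\t", quote = FALSE)

  ts <- data.table::data.table(sample_id = names(tr$labels),
                               subtype = tr$labels,
                               instability = tr$instability,
                               hazard = tr$hazard)
  data.table::fwrite(ts, paths["truth_samples"], sep = "\t", quote = FALSE)
  genes <- co$annotation$symbol
  tg <- data.table::data.table(
    gene = genes,
    dosage = as.integer(genes %in% tr$dosage_genes),
    silenced = as.integer(genes %in% tr$silenced_genes),
    survival_linked = as.integer(genes %in% tr$survival_linked_genes))
  data.table::fwrite(tg, paths["truth_genes"], sep = "\t", quote = FALSE)
  invisible(paths)
}
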