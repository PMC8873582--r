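#' Default pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic-cohort configuration (or
#' an input directory of previously written cohort files), the correlation
#' and survival thresholds, the NMF and integrative-clustering settings, the
#' aberration thresholds and the output directory. One global `seed` expands
#' to fixed per-stage seeds (`seed + 100 * stage_index`) so stages are
#' independently reproducible.
#'
#' @param cohort [cohort_config()] for synthetic mode, or `NULL` when
#'   `cohort_dir` points at existing input files.
#' @param cohort_dir Directory of cohort files written by [write_cohort()].
#' @param out_dir Output directory.
#' @param alpha_cor,alpha_surv Thresholds for [select_cor_genes()].
#' @param nmf_k_range,nmf_runs,nmf_max_iter,nmf_tol NMF consensus settings.
#' @param nmf_fixed_k Skip model selection and use this k (NULL = select).
#' @param icluster_k,icluster_lambda,icluster_n_init Integrative settings.
#' @param thresholds [aberration_thresholds()].
#' @param probe_rule Representative-probe rule, `"min_r"` or `"mean_r"`.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), cohort_dir = NULL,
                            out_dir = tempfile("momsub_run_"),
                            alpha_cor = 0.05, alpha_surv = 0.05,
                            nmf_k_range = 2:10, nmf_runs = 50,
                            nmf_max_iter = 2000, nmf_tol = 1e-6,
                            nmf_fixed_k = NULL,
                            icluster_k = 3, icluster_lambda = 0.2,
                            icluster_n_init = 20,
                            thresholds = aberration_thresholds(),
                            probe_rule = "min_r", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "nmf_cnv", "nmf_met", "icluster",
                        "aberration", "characterize"))
  (seed + 100L * idx) %% .Machine$integer.max
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reconstructs the matched cohort from its on-disk form: the expression
#' matrix, gene-level copy number re-mapped from the SEG segments, the
#' probe-level methylation layers with their manifest, clinical survival and
#' the binary mutation matrix from MAF-lite records.
#'
#' @param dir Directory holding the cohort files.
#' @return List with `layers`, `survival`, `clinical`, `mutations`,
#'   `annotation`, `manifest`.
#' @export
read_cohort_dir <- function(dir) {
  exp <- read_layer(file.path(dir, "exp.tsv"), "EXP", centered = TRUE)
  ann <- data.table::fread(file.path(dir, "genes.tsv"), data.table = FALSE)
  seg <- read_seg(file.path(dir, "cnv.seg"))
  cnv <- map_segments_to_genes(seg, ann)
  probes_beta <- read_layer(file.path(dir, "met_probes_beta.tsv"), "MET",
                            centered = FALSE, scale = "beta")
  probes_met <- read_layer(file.path(dir, "met_probes_centered.tsv"), "MET",
                           centered = TRUE, scale = "M")
  manifest <- data.table::fread(file.path(dir, "manifest.tsv"), data.table = FALSE)
  clin <- data.table::fread(file.path(dir, "clinical.tsv"), data.table = FALSE)
  survival <- data.frame(sample_id = clin$sample_id, time = clin$os_days,
                         event = clin$os_event, stringsAsFactors = FALSE)
  maf <- data.table::fread(file.path(dir, "mutations_maf.tsv"), data.table = FALSE)
  mut <- mutation_matrix(maf, samples = survival$sample_id)
  list(layers = list(exp = exp, cnv = cnv, probes_met = probes_met,
                     probes_beta = probes_beta),
       survival = survival,
       clinical = clin[, setdiff(names(clin), c("os_days", "os_event"))],
       mutations = mut, annotation = ann, manifest = manifest)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

#' Run the full subtyping pipeline
#'
#' Executes, in order: cohort input (synthetic generation or reading a
#' cohort directory), CNVcor/METcor gene selection, NMF consensus subtyping
#' on the CNVcor and METcor expression features, integrative clustering of
#' the expression/copy-number/methylation layers over the selected genes,
#' aberration-frequency coupling, and subtype characterization. All stage
#' tables are written as TSV under `config$out_dir` together with a JSON run
#' manifest (parameters, seeds, wall time).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory results plus
#'   `artifacts`, the named vector of written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- c()

  ## stage: cohort --------------------------------------------------------
  if (!is.null(config$cohort_dir)) {
    if (!dir.exists(config$cohort_dir))
      stop("[cohort] input directory not found: ", config$cohort_dir)
    co <- read_cohort_dir(config$cohort_dir)
    truth <- NULL
  } else {
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, "simulate")
    sim <- generate_cohort(cc)
    co <- sim$cohort
    truth <- sim$truth
  }
  matched <- match_samples(co$layers, co$survival, co$mutations)
  layers <- matched$layers
  survival <- matched$survival

  ## stage: cor_genes -----------------------------------------------------
  met_gene <- select_representative_probe(layers$probes_met, layers$exp,
                                          co$manifest, rule = config$probe_rule)
  chosen <- attr(met_gene, "chosen_probes")
  cnv_cor <- correlate_layers(layers$exp, layers$cnv)
  met_cor <- correlate_layers(layers$exp, met_gene)
  lr <- logrank_expression_filter(layers$exp, survival)
  cnv_cor$p_logrank <- lr$p_logrank[match(cnv_cor$gene, lr$gene)]
  met_cor$p_logrank <- lr$p_logrank[match(met_cor$gene, lr$gene)]
  sets <- select_cor_genes(cnv_cor, met_cor, alpha_cor = config$alpha_cor,
                           alpha_surv = config$alpha_surv)
  sk_cnv <- skewness_with_test(cnv_cor$z)
  sk_met <- skewness_with_test(met_cor$z)
  cnv_cor$layer <- "CNV"; met_cor$layer <- "MET"
  art["correlations"] <- write_tsv(rbind(cnv_cor, met_cor),
                                   file.path(config$out_dir, "gene_correlations.tsv"))
  art["cor_sets"] <- write_tsv(
    data.frame(gene = c(sets$cnvcor, sets$metcor),
               set = rep(c("CNVcor", "METcor"),
                         c(length(sets$cnvcor), length(sets$metcor)))),
    file.path(config$out_dir, "cor_gene_sets.tsv"))
  art["arm_proportions"] <- write_tsv(
    rbind(cbind(set = "CNVcor", arm_proportions(sets$cnvcor, co$annotation)),
          cbind(set = "METcor", arm_proportions(sets$metcor, co$annotation))),
    file.path(config$out_dir, "arm_proportions.tsv"))
  if (!length(sets$cnvcor) || !length(sets$metcor))
    stop("[cor_genes] empty CNVcor or METcor set; relax thresholds")

  ## stage: nmf_consensus ---------------------------------------------------
  nmf_one <- function(genes, stage) {
    V <- to_nonnegative(layers$exp$values[genes, , drop = FALSE])
    sd_ <- stage_seed(config$seed, stage)
    if (is.null(config$nmf_fixed_k)) {
      sel <- select_k(V, k_range = config$nmf_k_range, n_runs = config$nmf_runs,
                      seed = sd_, max_iter = config$nmf_max_iter,
                      tol = config$nmf_tol)
      res <- sel$results[[paste0("k", sel$best_k)]]
      list(res = res, diagnostics = sel$diagnostics, best_k = sel$best_k)
    } else {
      res <- consensus_cluster(V, config$nmf_fixed_k, n_runs = config$nmf_runs,
                               seed = sd_, max_iter = config$nmf_max_iter,
                               tol = config$nmf_tol)
      list(res = res, diagnostics = NULL, best_k = config$nmf_fixed_k)
    }
  }
  nmf_cnv <- nmf_one(sets$cnvcor, "nmf_cnv")
  nmf_met <- nmf_one(sets$metcor, "nmf_met")
  art["nmf_labels"] <- write_tsv(
    data.frame(sample_id = matched$sample_ids,
               subtype_cnvcor = nmf_cnv$res$labels,
               subtype_metcor = nmf_met$res$labels),
    file.path(config$out_dir, "nmf_labels.tsv"))
  if (!is.null(nmf_cnv$diagnostics))
    art["nmf_diagnostics"] <- write_tsv(
      rbind(cbind(features = "CNVcor", nmf_cnv$diagnostics),
            cbind(features = "METcor", nmf_met$diagnostics)),
      file.path(config$out_dir, "nmf_diagnostics.tsv"))

  ## stage: integrative_cluster ---------------------------------------------
  union_genes <- union(sets$cnvcor, sets$metcor)
  ic_layers <- list(
    exp = omics_layer(layers$exp$values[union_genes, , drop = FALSE], "EXP",
                      centered = TRUE),
    cnv = omics_layer(layers$cnv$values[
      intersect(union_genes, feature_ids(layers$cnv)), , drop = FALSE], "CNV",
      centered = TRUE),
    met = omics_layer(met_gene$values[
      intersect(union_genes, feature_ids(met_gene)), , drop = FALSE], "MET",
      centered = TRUE, scale = "M"))
  ic <- icluster_fit(ic_layers, k = config$icluster_k,
                     lambda = config$icluster_lambda,
                     n_init = config$icluster_n_init,
                     seed = stage_seed(config$seed, "icluster"))
  art["icluster_labels"] <- write_tsv(
    data.frame(sample_id = matched$sample_ids, subtype = ic$labels),
    file.path(config$out_dir, "icluster_labels.tsv"))

  ## stage: aberration_stats --------------------------------------------------
  beta_gene <- layers$probes_beta$values[chosen$probe_id, , drop = FALSE]
  rownames(beta_gene) <- chosen$gene
  calls <- call_aberrations(
    cnv = layers$cnv,
    met_beta = omics_layer(beta_gene, "MET", centered = FALSE, scale = "beta"),
    thresholds = config$thresholds)
  prof <- frequency_profile(calls)
  freq_cor <- pairwise_frequency_correlation(prof)
  art["aberration_frequencies"] <- write_tsv(
    prof, file.path(config$out_dir, "aberration_frequencies.tsv"))
  art["aberration_correlations"] <- write_tsv(
    freq_cor, file.path(config$out_dir, "aberration_correlations.tsv"))

  ## stage: subtype_characterize ----------------------------------------------
  labs <- ic$labels
  km <- km_estimator(survival, labs)
  lr_sub <- logrank_test(survival, labs)
  conc <- list(
    cnv_met = concordance(nmf_cnv$res$labels, nmf_met$res$labels),
    ic_cnv = concordance(labs, nmf_cnv$res$labels),
    ic_met = concordance(labs, nmf_met$res$labels))
  # compare the best- and worst-survival subtypes (KM median; never-crossing
  # curves count as best, event-rate fallback when no median is defined)
  med <- km_median(survival, labs)
  score <- ifelse(is.na(med), Inf, med)
  if (!any(is.finite(score)))
    score <- -vapply(split(survival$event, labs), mean, 0)[names(med)]
  two <- names(score)[c(which.max(score), which.min(score))]
  if (two[1] == two[2]) two <- names(score)[1:2]
  in_two <- labs %in% two
  cnv_cat <- categorize_omics(omics_layer(
    layers$cnv$values[intersect(sets$cnvcor, feature_ids(layers$cnv)),
                      in_two, drop = FALSE], "CNV", centered = TRUE),
    thresholds = config$thresholds)
  met_cat <- categorize_omics(omics_layer(
    beta_gene[intersect(sets$metcor, rownames(beta_gene)), in_two, drop = FALSE],
    "MET", centered = FALSE, scale = "beta"), thresholds = config$thresholds)
  screen <- three_level_screen(
    omics_layer(layers$exp$values[union_genes, in_two, drop = FALSE], "EXP",
                centered = TRUE),
    cnv_cat, met_cat, labs[in_two],
    seed = stage_seed(config$seed, "characterize"))
  mut_diff <- differential_mutation_test(matched$mutations[, in_two, drop = FALSE],
                                         labs[in_two])
  clin <- clinical_table(labs, co$clinical[match(matched$sample_ids,
                                                 co$clinical$sample_id), ])
  tert <- NULL
  if (length(screen$genes)) {
    g <- screen$genes[1]
    tert <- tertile_survival(layers$exp$values[g, ], survival)
    tert$gene <- g
  }
  art["km_curves"] <- write_tsv(km, file.path(config$out_dir, "km_curves.tsv"))
  art["mutation_differential"] <- write_tsv(
    mut_diff, file.path(config$out_dir, "mutation_differential.tsv"))
  art["category_differential"] <- write_tsv(
    rbind(screen$cnv, screen$met),
    file.path(config$out_dir, "category_differential.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("momsub")),
    seed = config$seed,
    parameters = list(alpha_cor = config$alpha_cor, alpha_surv = config$alpha_surv,
                      nmf_k_range = config$nmf_k_range, nmf_runs = config$nmf_runs,
                      icluster_k = config$icluster_k,
                      icluster_lambda = config$icluster_lambda,
                      thresholds = config$thresholds),
    skewness = list(cnv = sk_cnv, met = sk_met),
    nmf_best_k = list(cnvcor = nmf_cnv$best_k, metcor = nmf_met$best_k),
    logrank_subtypes = lr_sub,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = co, truth = truth, matched = matched,
                 correlations = list(cnv = cnv_cor, met = met_cor),
                 skewness = list(cnv = sk_cnv, met = sk_met),
                 sets = sets, met_gene = met_gene,
                 nmf = list(cnvcor = nmf_cnv, metcor = nmf_met),
                 icluster = ic, aberration = list(profile = prof, cor = freq_cor),
                 characterize = list(km = km, logrank = lr_sub,
                                     concordance = conc, screen = screen,
                                     mutation = mut_diff, clinical = clin,
                                     tertile = tert, compared = two),
                 artifacts = art))
}
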