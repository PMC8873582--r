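#' Kaplan-Meier estimate per group
#'
#' Product-limit survival curves, one per label group, via
#' [survival::survfit()]. Empty groups are omitted.
#'
#' @param survival data.frame with `time` (> 0) and `event` (0/1).
#' @param labels Group label per record.
#' @return data.frame (group, time, n_risk, n_event, surv).
#' @export
km_estimator <- function(survival, labels) {
  stopifnot(nrow(survival) == length(labels), all(survival$time > 0))
  grp <- factor(labels)
  fit <- survival::survfit(survival::Surv(survival$time, survival$event) ~ grp)
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(levels(grp)[1], length(s$time))
            else sub("^grp=", "", as.character(s$strata))
  data.frame(group = strata, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, stringsAsFactors = FALSE)
}

#' Median survival per group
#'
#' @inheritParams km_estimator
#' @return Named numeric vector of KM median survival times (NA when the
#'   curve never crosses 0.5).
#' @export
km_median <- function(survival, labels) {
  grp <- factor(labels)
  fit <- survival::survfit(survival::Surv(survival$time, survival$event) ~ grp)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {
    stats::setNames(tab["median"], levels(grp))
  } else {
    stats::setNames(tab[, "median"], sub("^grp=", "", rownames(tab)))
  }
}

#' g-group log-rank test
#'
#' Standard log-rank statistic over `g` groups with `g - 1` degrees of
#' freedom, via [survival::survdiff()].
#'
#' @inheritParams km_estimator
#' @return List: `chi2`, `df`, `p`.
#' @export
logrank_test <- function(survival, labels) {
  grp <- factor(labels)
  if (nlevels(droplevels(grp)) < 2) stop("log-rank test needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(survival$time, survival$event) ~ grp)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Concordance between two labelings
#'
#' Cross-tabulation with a chi-square test of independence (no continuity
#' correction) and the adjusted Rand index. For a degenerate single-class
#' labeling the chi-square is omitted and only the ARI reported.
#'
#' @param labels_a,labels_b Label vectors over the same samples.
#' @return List: `table`, `chi2`, `p`, `ari`.
#' @export
concordance <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  ari <- mclust::adjustedRandIndex(labels_a, labels_b)
  if (min(dim(tab)) < 2)
    return(list(table = tab, chi2 = NA_real_, p = NA_real_, ari = ari))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic), p = ct$p.value, ari = ari)
}

#' Categorize omics values as Normal / Gain / Loss or Normal / HyperMethy / HypoMethy
#'
#' Each cell receives exactly one category using the directional aberration
#' thresholds (strict inequalities).
#'
#' @param layer CNV [omics_layer()] (log2 ratios) or uncentered MET layer
#'   (beta values); plain matrices are accepted with `kind` given.
#' @param kind `"CNV"` or `"MET"`; inferred from an [omics_layer()].
#' @param thresholds See [aberration_thresholds()].
#' @return Character matrix of categories, same dimnames as the input.
#' @export
categorize_omics <- function(layer, kind = NULL,
                             thresholds = aberration_thresholds()) {
  if (inherits(layer, "omics_layer")) kind <- layer$kind
  kind <- match.arg(kind, c("CNV", "MET"))
  calls <- if (kind == "CNV") call_aberrations(cnv = layer, thresholds = thresholds)$cnv
           else call_aberrations(met_beta = layer, thresholds = thresholds)$met
  lv <- if (kind == "CNV") c("Loss", "Normal", "Gain")
        else c("HypoMethy", "Normal", "HyperMethy")
  out <- matrix(lv[calls + 2L], nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  out
}

.bh <- function(p) stats::p.adjust(p, method = "BH")

#' Per-gene categorical differential test between two subtypes
#'
#' For each gene, a group x category contingency table (empty categories
#' dropped) tested by Fisher's exact test — full enumeration when the total
#' count is at most `exact_max`, otherwise a seeded Monte-Carlo exact test —
#' with BH adjustment across genes. The direction is the group with the
#' higher fraction of non-Normal cells.
#'
#' @param categories Character matrix from [categorize_omics()].
#' @param labels Subtype label per sample (exactly two distinct values after
#'   restriction).
#' @param exact_max Largest table total for full enumeration (default 200).
#' @param mc_tables Monte-Carlo tables beyond that (default 1e5).
#' @param seed Seed for the Monte-Carlo branch.
#' @return data.frame (gene, test, p, q, direction).
#' @export
differential_category_test <- function(categories, labels, exact_max = 200,
                                       mc_tables = 1e5, seed = 1) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two subtypes required")
  set.seed(seed)
  genes <- rownames(categories)
  p <- numeric(length(genes))
  dir <- character(length(genes))
  for (i in seq_along(genes)) {
    tab <- table(labels, categories[i, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) { p[i] <- 1 } else if (sum(tab) <= exact_max) {
      p[i] <- stats::fisher.test(tab)$p.value
    } else {
      p[i] <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_tables)$p.value
    }
    ab <- 1 - tab[, colnames(tab) == "Normal", drop = FALSE] / rowSums(tab)
    frac <- if (ncol(ab)) ab[, 1] else rowSums(tab) * 0
    dir[i] <- groups[which.max(frac[groups])]
  }
  data.frame(gene = genes, test = "fisher_category", p = p, q = .bh(p),
             direction = dir, stringsAsFactors = FALSE)
}

#' Per-gene mutation differential test between two subtypes
#'
#' 2x2 Fisher exact test (mutated/wild x group) per gene with BH adjustment;
#' genes never mutated in the restricted samples are skipped.
#'
#' @param mutations Binary gene x sample matrix.
#' @param labels Subtype label per sample (two distinct values).
#' @return data.frame (gene, test, p, q, direction, rate_a, rate_b) where
#'   `direction` names the group with the higher mutation rate.
#' @export
differential_mutation_test <- function(mutations, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two subtypes required")
  keep <- rowSums(mutations) > 0
  if (!all(keep))
    message(sprintf("differential_mutation_test(): %d never-mutated genes skipped",
                    sum(!keep)))
  mut <- mutations[keep, , drop = FALSE]
  ga <- labels == groups[1]
  res <- t(apply(mut, 1, function(x) {
    tab <- matrix(c(sum(x[ga]), sum(ga) - sum(x[ga]),
                    sum(x[!ga]), sum(!ga) - sum(x[!ga])), 2, 2)
    c(p = stats::fisher.test(tab)$p.value,
      rate_a = mean(x[ga]), rate_b = mean(x[!ga]))
  }))
  data.frame(gene = rownames(mut), test = "fisher_mutation",
             p = res[, "p"], q = .bh(res[, "p"]),
             direction = ifelse(res[, "rate_a"] >= res[, "rate_b"],
                                groups[1], groups[2]),
             rate_a = res[, "rate_a"], rate_b = res[, "rate_b"],
             stringsAsFactors = FALSE)
}

#' Expression-tertile survival analysis for one gene
#'
#' Splits samples into low/moderate/high (L1-L3) expression tertiles at the
#' 1/3 and 2/3 empirical quantiles and runs a 3-group log-rank test. When
#' heavy ties leave a tertile empty, assignment falls back to ranks; a
#' constant expression vector is degenerate and reported with p = 1.
#'
#' @param x Expression values for one gene (>= 9 samples).
#' @param survival data.frame with `time`, `event`, aligned with `x`.
#' @return List: `labels` (L1/L2/L3), `group_sizes`, `p`, `median_survival`,
#'   `degenerate`, `fallback`.
#' @export
tertile_survival <- function(x, survival) {
  n <- length(x)
  stopifnot(n >= 9, nrow(survival) == n)
  q <- stats::quantile(x, c(1 / 3, 2 / 3), type = 7)
  lab <- if (q[1] < q[2]) {
    cut(x, c(-Inf, q[1], q[2], Inf), labels = c("L1", "L2", "L3"))
  } else {
    factor(rep("L1", n), levels = c("L1", "L2", "L3"))  # forces the fallback
  }
  fallback <- FALSE
  degenerate <- FALSE
  if (any(table(lab) == 0)) {
    fallback <- TRUE
    r <- rank(x, ties.method = "first")
    lab <- cut(r, stats::quantile(r, c(0, 1 / 3, 2 / 3, 1), type = 7),
               labels = c("L1", "L2", "L3"), include.lowest = TRUE)
    if (stats::sd(x) == 0) degenerate <- TRUE
  }
  p <- if (degenerate) 1 else logrank_test(survival, lab)$p
  list(labels = lab, group_sizes = table(lab), p = p,
       median_survival = km_median(survival, lab),
       degenerate = degenerate, fallback = fallback)
}

#' Subtype-by-covariate clinical summary
#'
#' Count table per categorical covariate against the subtype labels, each
#' with a chi-square independence test (no continuity correction).
#'
#' @param labels Subtype label per sample.
#' @param clinical data.frame of categorical covariates (a `sample_id`
#'   column, if present, is ignored).
#' @return List with `tables` (named list of contingency tables) and `p`
#'   (named vector of chi-square p-values).
#' @export
clinical_table <- function(labels, clinical) {
  covars <- setdiff(names(clinical), "sample_id")
  tabs <- lapply(covars, function(v) table(clinical[[v]], labels))
  names(tabs) <- covars
  p <- vapply(tabs, function(tb) {
    if (min(dim(tb)) < 2) return(NA_real_)
    suppressWarnings(stats::chisq.test(tb, correct = FALSE)$p.value)
  }, 0)
  list(tables = tabs, p = p)
}

#' Three-level differential screen between two subtypes
#'
#' Genes different between two subtypes at all three levels: categorical
#' copy-number Fisher test, categorical methylation Fisher test, and a
#' Wilcoxon rank-sum test on expression (a nonparametric stand-in for a
#' count-model differential-expression step), each at FDR `q_max`;
#' the intersection is returned.
#'
#' @param exp_layer EXP [omics_layer()].
#' @param cnv_categories,met_categories Matrices from [categorize_omics()].
#' @param labels Subtype labels (two groups after restriction).
#' @param q_max BH FDR threshold (default 0.1).
#' @param seed Passed to [differential_category_test()].
#' @return List with the three per-gene tables and `genes`, the intersection.
#' @export
three_level_screen <- function(exp_layer, cnv_categories, met_categories,
                               labels, q_max = 0.1, seed = 1) {
  cnv <- differential_category_test(cnv_categories, labels, seed = seed)
  met <- differential_category_test(met_categories, labels, seed = seed + 1)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  ga <- labels == groups[1]
  ev <- exp_layer$values
  pw <- apply(ev, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[ga], x[!ga])$p.value))
  up <- rowMeans(ev[, ga, drop = FALSE]) >= rowMeans(ev[, !ga, drop = FALSE])
  expr <- data.frame(gene = rownames(ev), test = "wilcoxon_expression",
                     p = pw, q = .bh(pw),
                     direction = ifelse(up, groups[1], groups[2]),
                     stringsAsFactors = FALSE)
  hits <- Reduce(intersect, list(cnv$gene[cnv$q < q_max],
                                 met$gene[met$q < q_max],
                                 expr$gene[expr$q < q_max]))
  list(cnv = cnv, met = met, expression = expr, genes = hits)
}
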