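#' Fisher Z transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform of the Pearson correlation.
#'
#' @param r Correlation(s) with |r| < 1.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z() requires |r| < 1")
  atanh(r)
}

# clamp before atanh so near-perfect correlations stay finite
.clamp_r <- function(r, eps = 1e-15) pmin(pmax(r, -1 + eps), 1 - eps)

#' Per-gene Pearson correlation between two omics layers
#'
#' For every gene shared by the two layers, the Pearson correlation between
#' the expression row and the other layer's row across the (identically
#' ordered) samples, the Fisher Z value (r clamped to +/-(1 - 1e-15) first),
#' and a two-sided p-value from the t distribution with n - 2 df.
#' Zero-variance rows are excluded and reported in the `"excluded"` attribute.
#'
#' @param exp_layer EXP [omics_layer()].
#' @param other CNV or MET [omics_layer()] with the same sample order.
#' @return data.frame (gene, r, z, p_cor), one row per usable shared gene.
#' @export
correlate_layers <- function(exp_layer, other) {
  stopifnot(inherits(exp_layer, "omics_layer"), inherits(other, "omics_layer"))
  if (!identical(sample_ids(exp_layer), sample_ids(other)))
    stop("layers must share an identical sample order")
  n <- ncol(exp_layer$values)
  if (n < 4) stop("need at least 4 samples")
  shared <- intersect(feature_ids(exp_layer), feature_ids(other))
  if (!length(shared)) stop("no shared genes")
  x <- exp_layer$values[shared, , drop = FALSE]
  y <- other$values[shared, , drop = FALSE]
  if (anyNA(x) || anyNA(y)) stop("impute missing values before correlating")
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- rowSums(xc^2)
  sy <- rowSums(yc^2)
  ok <- sx > 0 & sy > 0
  r <- rowSums(xc * yc)[ok] / sqrt(sx[ok] * sy[ok])
  r <- pmin(pmax(r, -1), 1)
  rc <- .clamp_r(r)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  out <- data.frame(gene = shared[ok], r = r, z = atanh(rc),
                    p_cor = 2 * stats::pt(-abs(tstat), df = n - 2),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- shared[!ok]
  out
}

#' Adjusted Fisher-Pearson skewness with the D'Agostino test
#'
#' Returns the adjusted sample skewness
#' `G1 = m3 / m2^(3/2) * sqrt(n (n-1)) / (n - 2)` and the two-sided p-value of
#' the D'Agostino skewness normality test (requires n >= 8; `p` is `NA`
#' below that).
#'
#' @param x Numeric vector, not constant.
#' @return List with `g1` and `p`.
#' @export
skewness_with_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite values")
  if (stats::sd(x) == 0) stop("constant vector has undefined skewness")
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  b1 <- m3 / m2^1.5
  g1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  p <- NA_real_
  if (n >= 8) {
    # D'Agostino (1970) transformation of sqrt(b1) to an approximate normal
    y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
      ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    w2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(log(sqrt(w2)))
    alpha <- sqrt(2 / (w2 - 1))
    z <- delta * asinh(y / alpha)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(g1 = g1, p = p)
}

#' Per-gene log-rank survival filter on dichotomized expression
#'
#' Splits samples at each gene's median expression (above vs at-or-below) and
#' runs a two-group log-rank test against overall survival. Degenerate splits
#' (constant expression, or a group smaller than 2) are recorded with p = 1
#' and flagged.
#'
#' @param exp_layer EXP [omics_layer()].
#' @param survival data.frame with `sample_id`, `time`, `event` covering the
#'   layer's samples.
#' @param split Grouping rule; `"median"` (default) or `"tertile"` (top vs
#'   bottom tertile).
#' @return data.frame (gene, p_logrank, degenerate).
#' @export
logrank_expression_filter <- function(exp_layer, survival,
                                      split = c("median", "tertile")) {
  split <- match.arg(split)
  sv <- survival[match(sample_ids(exp_layer), survival$sample_id), ]
  if (anyNA(sv$time)) stop("survival records missing for some samples")
  m <- exp_layer$values
  res <- data.frame(gene = rownames(m), p_logrank = 1, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    grp <- if (split == "median") {
      x > stats::median(x)
    } else {
      q <- stats::quantile(x, c(1 / 3, 2 / 3), type = 7)
      keep <- x <= q[1] | x > q[2]
      x > q[2]
    }
    if (split == "tertile") {
      gi <- grp[keep]; svi <- sv[keep, ]
    } else {
      gi <- grp; svi <- sv
    }
    if (length(unique(gi)) < 2 || min(table(gi)) < 2) {
      res$degenerate[i] <- TRUE
      next
    }
    res$p_logrank[i] <- logrank_test(svi, as.integer(gi) + 1L)$p
  }
  res
}

#' Select CNVcor and METcor gene sets
#'
#' CNVcor genes correlate positively with copy number; METcor genes correlate
#' negatively with methylation; both must pass the correlation threshold and
#' (when supplied) the survival filter.
#'
#' @param cnv_cor,met_cor data.frames from [correlate_layers()], optionally
#'   carrying a `p_logrank` column (see [logrank_expression_filter()]).
#' @param alpha_cor Correlation p threshold (default 0.05, unadjusted; set
#'   `adjust = "BH"` to threshold BH-adjusted values instead).
#' @param alpha_surv Survival p threshold; `NULL` (or >= 1) disables the
#'   survival filter.
#' @param adjust `"none"` or `"BH"`.
#' @return List of class `cor_gene_sets`: `cnvcor`, `metcor`, `overlap`.
#' @export
select_cor_genes <- function(cnv_cor, met_cor, alpha_cor = 0.05,
                             alpha_surv = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pick <- function(tab, positive) {
    p <- if (adjust == "BH") stats::p.adjust(tab$p_cor, "BH") else tab$p_cor
    keep <- (if (positive) tab$r > 0 else tab$r < 0) & p < alpha_cor
    if (!is.null(alpha_surv) && alpha_surv < 1) {
      if (is.null(tab$p_logrank))
        stop("survival filter requested but no p_logrank column present")
      keep <- keep & tab$p_logrank < alpha_surv
    }
    tab$gene[keep]
  }
  cnvcor <- pick(cnv_cor, positive = TRUE)
  metcor <- pick(met_cor, positive = FALSE)
  structure(list(cnvcor = cnvcor, metcor = metcor,
                 overlap = intersect(cnvcor, metcor)),
            class = "cor_gene_sets")
}

#' Per-arm proportion of selected genes
#'
#' For each chromosome arm, the fraction of analyzed genes on that arm that
#' belong to the given gene set; arms with no analyzed genes are omitted.
#'
#' @param gene_set Character vector of gene symbols.
#' @param annotation data.frame with `symbol`, `chromosome`, `arm`.
#' @return data.frame (chromosome, arm, n_set, n_total, fraction).
#' @export
arm_proportions <- function(gene_set, annotation) {
  key <- paste0(annotation$chromosome, annotation$arm)
  tot <- table(key)
  hit <- table(factor(key[annotation$symbol %in% gene_set], levels = names(tot)))
  out <- data.frame(
    chromosome = sub("[pq]$", "", names(tot)),
    arm = sub("^.*(.)$", "\\1", names(tot)),
    n_set = as.integer(hit), n_total = as.integer(tot),
    fraction = as.numeric(hit) / as.numeric(tot),
    stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.integer(out$chromosome)), out$arm)
  out[ord, , drop = FALSE]
}

#' CpG-region and gene-relation breakdown of METcor genes
#'
#' Tallies the representative probes of the METcor genes by CpG region class
#' and by relation to the gene, plus coding/non-coding gene counts when an
#' annotation is supplied.
#'
#' @param metcor_genes Character vector of METcor gene symbols.
#' @param manifest Probe manifest (probe_id, gene_symbol, region_class,
#'   gene_relation).
#' @param chosen_probes data.frame (gene, probe_id) from the
#'   `"chosen_probes"` attribute of [select_representative_probe()].
#' @param annotation Optional gene annotation with `symbol` and `coding`.
#' @return List of tables: `region_class`, `gene_relation`, `coding`.
#' @export
cpg_region_breakdown <- function(metcor_genes, manifest, chosen_probes,
                                 annotation = NULL) {
  sel <- chosen_probes[chosen_probes$gene %in% metcor_genes, , drop = FALSE]
  key <- paste(manifest$probe_id, manifest$gene_symbol)
  idx <- match(paste(sel$probe_id, sel$gene), key)
  if (anyNA(idx)) stop("chosen probes missing from manifest")
  out <- list(
    region_class = table(manifest$region_class[idx]),
    gene_relation = table(manifest$gene_relation[idx]))
  if (!is.null(annotation)) {
    coding <- annotation$coding[match(sel$gene, annotation$symbol)]
    out$coding <- table(factor(ifelse(coding, "coding", "non-coding"),
                               levels = c("coding", "non-coding")))
  }
  out
}
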