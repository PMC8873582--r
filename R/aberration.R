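#' Default directional aberration thresholds
#'
#' Copy-number gain/loss thresholds apply to log2 segment means; the
#' hyper/hypomethylation thresholds apply to raw beta values — the two
#' scales are deliberately distinct.
#'
#' @param gain,loss Log2 copy-ratio cutoffs (gain positive, loss negative).
#' @param hyper,hypo Beta-value cutoffs for hyper/hypomethylation.
#' @export
aberration_thresholds <- function(gain = 0.3, loss = -0.3,
                                  hyper = 0.8, hypo = 0.2) {
  stopifnot(gain > 0, loss < 0, hyper > hypo)
  list(gain = gain, loss = loss, hyper = hyper, hypo = hypo)
}

#' Call directional copy-number and methylation aberrations
#'
#' Strict inequalities: a gene is a gain when its log2 copy ratio exceeds
#' `gain`, a loss below `loss`; hypermethylated when beta exceeds `hyper`,
#' hypomethylated below `hypo`; anything else is Normal. Supplying a
#' centered (or otherwise out-of-\[0,1\]) methylation matrix is an error —
#' the calls are defined on raw beta values.
#'
#' @param cnv CNV [omics_layer()] (log2 ratio units).
#' @param met_beta Uncentered MET [omics_layer()] with beta values.
#' @param thresholds See [aberration_thresholds()].
#' @return List of integer matrices `cnv` and `met` with values
#'   1 (gain/hyper), -1 (loss/hypo), 0 (Normal).
#' @export
call_aberrations <- function(cnv = NULL, met_beta = NULL,
                             thresholds = aberration_thresholds()) {
  out <- list()
  if (!is.null(cnv)) {
    v <- if (inherits(cnv, "omics_layer")) cnv$values else cnv
    out$cnv <- (v > thresholds$gain) - (v < thresholds$loss)
    storage.mode(out$cnv) <- "integer"
  }
  if (!is.null(met_beta)) {
    v <- if (inherits(met_beta, "omics_layer")) met_beta$values else met_beta
    if (inherits(met_beta, "omics_layer") &&
        (isTRUE(met_beta$centered) || identical(met_beta$scale, "M")))
      stop("call_aberrations() needs raw beta values, not centered/M values")
    if (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1)
      stop("methylation values outside [0, 1]: wrong scale supplied")
    out$met <- (v > thresholds$hyper) - (v < thresholds$hypo)
    storage.mode(out$met) <- "integer"
  }
  if (!length(out)) stop("supply at least one layer")
  out
}

#' Per-sample aberration frequency profile
#'
#' Fraction of analyzed genes called gain/loss (CNV) and hyper/hypo (MET)
#' in each sample.
#'
#' @param calls Result of [call_aberrations()].
#' @return data.frame (sample_id, f_gain, f_loss, f_hyper, f_hypo); columns
#'   for absent layers are omitted.
#' @export
frequency_profile <- function(calls) {
  ids <- colnames(if (!is.null(calls$cnv)) calls$cnv else calls$met)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(calls$cnv)) {
    out$f_gain <- colMeans(calls$cnv == 1L, na.rm = TRUE)
    out$f_loss <- colMeans(calls$cnv == -1L, na.rm = TRUE)
  }
  if (!is.null(calls$met)) {
    met <- calls$met[, ids, drop = FALSE]
    out$f_hyper <- colMeans(met == 1L, na.rm = TRUE)
    out$f_hypo <- colMeans(met == -1L, na.rm = TRUE)
  }
  out
}

#' Pairwise correlation of aberration frequencies across samples
#'
#' Pearson correlation, with two-sided p, for every unordered pair of the
#' frequency columns in the profile. Zero-variance columns are flagged and
#' their pairs reported with `NA`.
#'
#' @param profiles data.frame from [frequency_profile()] (>= 4 samples).
#' @return data.frame (var1, var2, r, p, flagged).
#' @export
pairwise_frequency_correlation <- function(profiles) {
  vars <- setdiff(names(profiles), "sample_id")
  if (nrow(profiles) < 4) stop("need at least 4 samples")
  pairs <- utils::combn(vars, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- profiles[[pr[1]]]; y <- profiles[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(r = NA_real_, p = NA_real_, flagged = 1))
    ct <- stats::cor.test(x, y, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value, flagged = 0)
  })
  data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
             r = res["r", ], p = res["p", ],
             flagged = res["flagged", ] == 1,
             stringsAsFactors = FALSE)
}
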