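#' Read SEG-format copy-number segments
#'
#' Columns: Sample, Chromosome, Start, End, Segment_Mean. Coordinates are
#' treated as 1-based inclusive by default; set `dialect = "zero_half_open"`
#' for 0-based half-open input.
#'
#' @param path Path to a SEG TSV.
#' @param dialect Coordinate convention of the file.
#' @return data.frame with columns `sample_id`, `chromosome`, `start`, `end`,
#'   `segment_mean`.
#' @export
read_seg <- function(path, dialect = c("one_inclusive", "zero_half_open")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(dt) <- tolower(names(dt))
  need <- c("sample", "chromosome", "start", "end", "segment_mean")
  if (!all(need %in% names(dt)))
    stop("SEG file must have columns Sample, Chromosome, Start, End, Segment_Mean")
  out <- data.frame(sample_id = as.character(dt$sample),
                    chromosome = as.character(dt$chromosome),
                    start = as.integer(dt$start),
                    end = as.integer(dt$end),
                    segment_mean = as.numeric(dt$segment_mean),
                    stringsAsFactors = FALSE)
  if (dialect == "zero_half_open") {
    out$start <- out$start + 1L  # end already equals the last covered base
  }
  if (any(out$start > out$end)) stop("SEG record with start > end")
  out
}

#' Map copy-number segments to gene-level values
#'
#' For every gene and sample, the gene's value is the length-weighted mean of
#' the segment means of all segments overlapping the gene body (weights are
#' overlapping base pairs, coordinates 1-based inclusive). Genes with no
#' overlapping segment in a sample are missing there.
#'
#' @param segments data.frame as returned by [read_seg()].
#' @param annotation data.frame with columns `symbol`, `chromosome`, `start`,
#'   `end` (same assembly as the segments).
#' @return A CNV [omics_layer()] (genes x samples), possibly with missing cells.
#' @export
map_segments_to_genes <- function(segments, annotation) {
  stopifnot(all(c("symbol", "chromosome", "start", "end") %in% names(annotation)))
  samples <- sort(unique(segments$sample_id))
  genes <- as.character(annotation$symbol)
  if (anyDuplicated(genes)) stop("duplicate gene symbols in annotation")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chromosome),
    ranges = IRanges::IRanges(annotation$start, annotation$end))
  seg_gr <- GenomicRanges::GRanges(
    seqnames = as.character(segments$chromosome),
    ranges = IRanges::IRanges(segments$start, segments$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(gene_gr)[qh], IRanges::ranges(seg_gr)[sh])
  w <- as.numeric(IRanges::width(ov))
  dt <- data.table::data.table(
    gene = qh,
    sample = match(segments$sample_id[sh], samples),
    wm = w * segments$segment_mean[sh],
    w = w)
  agg <- dt[, list(v = sum(wm) / sum(w)), by = c("gene", "sample")]
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(agg$gene, agg$sample)] <- agg$v
  omics_layer(m, kind = "CNV", centered = TRUE)
}

#' Collapse probe-level methylation to gene level by a representative probe
#'
#' For genes covered by several probes, one probe is chosen per gene by its
#' Pearson correlation with the gene's expression: under `min_r` the probe
#' with the smallest (most negative) correlation, under `mean_r` the probe
#' whose correlation is closest to the per-gene mean correlation. The chosen
#' probe's full row becomes the gene's row; provenance is kept in the
#' `"chosen_probes"` attribute.
#'
#' @param probe_layer MET [omics_layer()], probes x samples.
#' @param exp_layer EXP [omics_layer()] sharing the sample set/order.
#' @param manifest data.frame with one row per probe-gene pair: columns
#'   `probe_id`, `gene_symbol` (plus optional `region_class`, `gene_relation`).
#' @param rule `"min_r"` (default) or `"mean_r"`.
#' @return Gene-level MET [omics_layer()]; attribute `chosen_probes` is a
#'   data.frame (gene, probe_id, r). Genes with no probe in the layer or no
#'   expression row are excluded.
#' @export
select_representative_probe <- function(probe_layer, exp_layer, manifest,
                                        rule = c("min_r", "mean_r")) {
  rule <- match.arg(rule)
  stopifnot(identical(sample_ids(probe_layer), sample_ids(exp_layer)))
  man <- manifest[manifest$probe_id %in% feature_ids(probe_layer) &
                    manifest$gene_symbol %in% feature_ids(exp_layer), , drop = FALSE]
  genes <- sort(unique(as.character(man$gene_symbol)))
  if (!length(genes)) stop("no gene with both a probe row and an expression row")
  pv <- probe_layer$values
  ev <- exp_layer$values
  chosen <- character(length(genes))
  rsel <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    probes <- unique(as.character(man$probe_id[man$gene_symbol == g]))
    if (length(probes) == 1L) {
      chosen[gi] <- probes
      rsel[gi] <- suppressWarnings(stats::cor(pv[probes, ], ev[g, ],
                                              use = "pairwise.complete.obs"))
      next
    }
    r <- vapply(probes, function(p)
      suppressWarnings(stats::cor(pv[p, ], ev[g, ], use = "pairwise.complete.obs")),
      numeric(1))
    r[is.na(r)] <- 0
    pick <- if (rule == "min_r") which.min(r) else which.min(abs(r - mean(r)))
    chosen[gi] <- probes[pick]
    rsel[gi] <- r[pick]
  }
  m <- pv[chosen, , drop = FALSE]
  rownames(m) <- genes
  out <- omics_layer(m, kind = "MET", centered = probe_layer$centered,
                     scale = probe_layer$scale)
  attr(out, "chosen_probes") <- data.frame(gene = genes, probe_id = chosen,
                                           r = rsel, stringsAsFactors = FALSE)
  out
}
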