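#' Construct an omics layer
#'
#' An `omics_layer` is the package's core container: one numeric matrix with
#' features (genes or probes) in rows and samples in columns, tagged with the
#' kind of measurement it holds and whether values are tumor-minus-normal
#' centered.
#'
#' @param values Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids). Missing cells are `NA`.
#' @param kind One of `"EXP"`, `"CNV"`, `"MET"`.
#' @param centered Logical; `TRUE` when values have had the per-feature
#'   normal-tissue mean removed. Uncentered MET layers must hold beta values
#'   in \[0, 1\]; centered MET values lie in \[-1, 1\] on the beta scale (the
#'   package also uses centered M-values, which are unbounded, flagged by
#'   `scale = "M"`).
#' @param scale For MET layers, `"beta"` or `"M"`; ignored otherwise.
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(values, kind = c("EXP", "CNV", "MET"),
                        centered = FALSE, scale = c("beta", "M")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (kind == "MET" && scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (!centered && (rng[1] < 0 || rng[2] > 1))
      stop("uncentered MET beta values must lie in [0, 1]")
    if (centered && (rng[1] < -1 || rng[2] > 1))
      stop("centered MET beta values must lie in [-1, 1]")
  }
  structure(list(kind = kind, values = values, centered = centered,
                 scale = if (kind == "MET") scale else NA_character_),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer %s%s> %d features x %d samples, %d missing\n",
              x$kind,
              if (isTRUE(x$centered)) " (centered)" else "",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

feature_ids <- function(layer) rownames(layer$values)
sample_ids <- function(layer) colnames(layer$values)

#' Read an omics matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Cells that read `NA` (or are empty) are kept as missing, never as zero.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams omics_layer
#' @return An [omics_layer()].
#' @export
read_layer <- function(path, kind = c("EXP", "CNV", "MET"),
                       centered = FALSE, scale = c("beta", "M")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), data.table = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("matrix TSV needs a feature id column plus >=1 sample column")
  ids <- as.character(dt[[1]])
  samples <- colnames(dt)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header of ", path)
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path)
  body <- dt[, -1, with = FALSE]
  bad <- which(!vapply(body, is.numeric, logical(1)))
  if (length(bad)) {
    col <- samples[bad[1]]
    v <- suppressWarnings(as.numeric(body[[bad[1]]]))
    row <- which(is.na(v) & !is.na(body[[bad[1]]]))[1]
    stop(sprintf("non-numeric cell in %s at feature '%s', sample column '%s'",
                 path, ids[row], col))
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, samples)
  omics_layer(m, kind = kind, centered = centered, scale = scale)
}

#' Write an omics layer (or any named numeric matrix) to TSV
#'
#' @param x An [omics_layer()] or a numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature_id") {
  m <- if (inherits(x, "omics_layer")) x$values else x
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Filter features by missingness and chromosome
#'
#' Removes features whose fraction of missing samples is strictly greater
#' than `max_missing_fraction` (a feature with exactly the threshold fraction
#' is retained), and optionally features not located on autosomes 1-22.
#'
#' @param layer An [omics_layer()].
#' @param annotation Optional data.frame with columns `feature_id` and
#'   `chromosome` (values `"1"`..`"22"`, `"X"`, `"Y"`); required when
#'   `drop_sex_chromosomes = TRUE`. Features absent from the annotation are
#'   dropped when the flag is set.
#' @param max_missing_fraction Maximum tolerated missing fraction in \[0, 1\].
#' @param drop_sex_chromosomes Drop features outside chromosomes 1-22.
#' @return Filtered [omics_layer()].
#' @export
filter_features <- function(layer, annotation = NULL, max_missing_fraction = 0.3,
                            drop_sex_chromosomes = FALSE) {
  stopifnot(inherits(layer, "omics_layer"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(layer$values))
  keep <- frac <= max_missing_fraction
  if (drop_sex_chromosomes) {
    if (is.null(annotation))
      stop("`annotation` with feature_id and chromosome is required to drop sex chromosomes")
    chr <- as.character(annotation$chromosome[match(feature_ids(layer),
                                                    annotation$feature_id)])
    keep <- keep & !is.na(chr) & chr %in% as.character(1:22)
  }
  if (!any(keep)) stop("all features removed by filter_features()")
  out <- layer
  out$values <- layer$values[keep, , drop = FALSE]
  out
}

#' Impute missing cells by k-nearest-neighbor features
#'
#' Each missing cell is replaced by the mean, at that sample, of the `k`
#' features nearest in Euclidean distance computed over jointly observed
#' samples (distances are normalized by the overlap size so features with
#' different missingness are comparable). When fewer than `k` usable
#' neighbors exist for a cell, the feature's observed row mean is used and a
#' warning is raised.
#'
#' @param layer An [omics_layer()]; every feature needs at least one observed value.
#' @param k Number of neighbor features (default 10).
#' @return The layer with no missing values.
#' @export
knn_impute <- function(layer, k = 10) {
  stopifnot(inherits(layer, "omics_layer"), k >= 1)
  m <- layer$values
  if (!anyNA(m)) return(layer)
  if (any(rowSums(!is.na(m)) == 0))
    stop("knn_impute(): some features have no observed values")
  miss_rows <- which(rowSums(is.na(m)) > 0)
  fallback_used <- FALSE
  obs <- !is.na(m)
  for (i in miss_rows) {
    xi <- m[i, ]
    # mean squared difference over jointly observed samples, per candidate row
    d2 <- rep(NA_real_, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      joint <- obs[i, ] & obs[j, ]
      if (!any(joint)) next
      d2[j] <- mean((xi[joint] - m[j, joint])^2)
    }
    for (s in which(is.na(m[i, ]))) {
      cand <- which(!is.na(d2) & obs[, s])
      if (length(cand) < k) {
        m[i, s] <- mean(xi, na.rm = TRUE)
        fallback_used <- TRUE
      } else {
        nn <- cand[order(d2[cand], cand)][seq_len(k)]
        m[i, s] <- mean(m[nn, s])
      }
    }
  }
  if (fallback_used)
    warning("knn_impute(): fewer than k usable neighbors for some cells; row-mean fallback used")
  out <- layer
  out$values <- m
  out
}

#' Restrict a matched cohort to the common samples
#'
#' Intersects sample ids across omics layers, the survival table and the
#' mutation matrix, and returns every component restricted to that
#' intersection in one shared column order.
#'
#' @param layers Named list of [omics_layer()] objects.
#' @param survival Optional data.frame with columns `sample_id`, `time`, `event`.
#' @param mutations Optional binary gene x sample matrix.
#' @return List with elements `layers`, `survival`, `mutations`, `sample_ids`.
#' @export
match_samples <- function(layers, survival = NULL, mutations = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  idsets <- lapply(layers, sample_ids)
  if (!is.null(survival)) idsets <- c(idsets, list(as.character(survival$sample_id)))
  if (!is.null(mutations)) idsets <- c(idsets, list(colnames(mutations)))
  if (length(idsets) < 2) stop("match_samples() needs at least two inputs")
  common <- Reduce(intersect, idsets)
  if (length(common) < 3)
    stop("sample intersection has fewer than 3 samples")
  common <- sort(common)
  layers <- lapply(layers, function(l) {
    l$values <- l$values[, common, drop = FALSE]
    l
  })
  if (!is.null(survival))
    survival <- survival[match(common, survival$sample_id), , drop = FALSE]
  if (!is.null(mutations))
    mutations <- mutations[, common, drop = FALSE]
  list(layers = layers, survival = survival, mutations = mutations,
       sample_ids = common)
}

#' Build a binary mutation matrix from MAF-lite records
#'
#' Keeps missense and nonsense records only (synonymous and other classes are
#' discarded) and marks a gene mutated in a sample if at least one qualifying
#' record exists.
#'
#' @param maf data.frame with columns `sample_id`, `gene_symbol`, `variant_class`.
#' @param samples Optional character vector fixing the column set/order.
#' @return Binary gene x sample matrix.
#' @export
mutation_matrix <- function(maf, samples = NULL) {
  stopifnot(all(c("sample_id", "gene_symbol", "variant_class") %in% names(maf)))
  keep <- tolower(maf$variant_class) %in% c("missense", "nonsense")
  maf <- maf[keep, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(as.character(maf$sample_id)))
  genes <- sort(unique(as.character(maf$gene_symbol)))
  m <- matrix(0L, length(genes), length(samples), dimnames = list(genes, samples))
  ok <- maf$sample_id %in% samples
  m[cbind(match(maf$gene_symbol[ok], genes), match(maf$sample_id[ok], samples))] <- 1L
  m
}
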