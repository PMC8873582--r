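#' Split a signed matrix into nonnegative rows
#'
#' Centered omics values are signed but NMF needs nonnegative input, so each
#' feature row `x` becomes two rows `max(x, 0)` and `max(-x, 0)` (suffixed
#' `.pos` / `.neg`); `pos - neg` reconstructs the original.
#'
#' @param x An [omics_layer()] or numeric matrix.
#' @return Nonnegative matrix with twice the rows; the `"source_feature"`
#'   attribute maps rows back to the original features.
#' @export
to_nonnegative <- function(x) {
  m <- if (inherits(x, "omics_layer")) x$values else x
  if (!all(is.finite(m))) stop("matrix must be finite")
  out <- rbind(pmax(m, 0), pmax(-m, 0))
  rownames(out) <- c(paste0(rownames(m), ".pos"), paste0(rownames(m), ".neg"))
  attr(out, "source_feature") <- rep(rownames(m), 2)
  out
}

#' KL-divergence NMF with Brunet multiplicative updates
#'
#' Factorizes a nonnegative matrix `V ~ W H` (`W`: features x k, `H`: k x
#' samples) by the classic multiplicative updates for the generalized
#' Kullback-Leibler divergence, from a uniform random initialization drawn
#' from `seed`. The objective is non-increasing at every iteration; the
#' per-iteration trace is returned.
#'
#' @param V Nonnegative matrix, no all-zero columns.
#' @param k Inner rank, `2 <= k < min(dim(V))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol Stopping rule: at most `max_iter` updates or relative
#'   objective change below `tol`.
#' @return List of class `nmf_fit`: `W`, `H`, `trace`, `k`, `seed`.
#' @export
nmf_brunet <- function(V, k, seed = 1, max_iter = 2000, tol = 1e-6) {
  if (any(V < 0) || !all(is.finite(V))) stop("V must be finite and nonnegative")
  if (any(colSums(V) == 0)) stop("V has all-zero columns")
  if (k < 2 || k >= min(dim(V))) stop("need 2 <= k < min(dim(V))")
  set.seed(seed)
  W0 <- matrix(stats::runif(nrow(V) * k), nrow(V), k)
  H0 <- matrix(stats::runif(k * ncol(V)), k, ncol(V))
  res <- nmf_kl_cpp(V, W0, H0, as.integer(max_iter), tol)
  dimnames(res$W) <- list(rownames(V), NULL)
  dimnames(res$H) <- list(NULL, colnames(V))
  structure(list(W = res$W, H = res$H, trace = as.numeric(res$trace),
                 k = k, seed = seed), class = "nmf_fit")
}

.hard_labels <- function(H) apply(H, 2, which.max)  # ties -> lowest index

#' Consensus clustering over random NMF restarts
#'
#' Runs `n_runs` seeded factorizations, takes hard labels per run by the
#' maximal `H` entry, and averages the sample co-membership indicators into a
#' consensus matrix `C`. Final labels come from average-linkage hierarchical
#' clustering of `1 - C` cut at `k`; the cophenetic correlation measures the
#' agreement between `1 - C` and the dendrogram's cophenetic distances, and
#' the mean silhouette width of the final labels uses `1 - C` as
#' dissimilarity.
#'
#' @inheritParams nmf_brunet
#' @param n_runs Number of random restarts (default 50).
#' @return List of class `consensus_result`: `k`, `consensus`, `cophenetic`,
#'   `mean_silhouette`, `labels`, `n_runs`, `n_degenerate_runs`.
#' @export
consensus_cluster <- function(V, k, n_runs = 50, seed = 1,
                              max_iter = 2000, tol = 1e-6) {
  n <- ncol(V)
  C <- matrix(0, n, n)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  degenerate <- 0L
  for (r in seq_len(n_runs)) {
    fit <- nmf_brunet(V, k, seed = run_seeds[r], max_iter = max_iter, tol = tol)
    lab <- .hard_labels(fit$H)
    if (length(unique(lab)) < k) degenerate <- degenerate + 1L
    C <- C + outer(lab, lab, "==")
  }
  if (degenerate > 0)
    message(sprintf("consensus_cluster(): %d/%d runs yielded fewer than %d clusters",
                    degenerate, n_runs, k))
  C <- C / n_runs
  dimnames(C) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  coph <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  if (is.na(coph)) coph <- 1  # constant dissimilarity: dendrogram is exact
  sil <- cluster::silhouette(labels, dmatrix = 1 - C)
  msil <- if (length(sil) == 1 && is.na(sil)) NA_real_ else mean(sil[, "sil_width"])
  structure(list(k = k, consensus = C, cophenetic = coph,
                 mean_silhouette = msil,
                 labels = stats::setNames(labels, colnames(V)),
                 n_runs = n_runs, n_degenerate_runs = degenerate),
            class = "consensus_result")
}

#' Choose the cluster count by cophenetic correlation
#'
#' Runs [consensus_cluster()] for each `k` in `k_range` and returns the
#' smallest `k` maximizing the cophenetic correlation (exact ties broken by
#' larger mean silhouette), together with the full diagnostic table.
#'
#' @inheritParams consensus_cluster
#' @param k_range Candidate cluster counts (default 2:10).
#' @return List: `best_k`, `diagnostics` (data.frame k / cophenetic /
#'   mean_silhouette), `results` (per-k [consensus_cluster()] output).
#' @export
select_k <- function(V, k_range = 2:10, n_runs = 50, seed = 1,
                     max_iter = 2000, tol = 1e-6) {
  if (max(k_range) >= min(dim(V))) stop("k_range exceeds matrix limits")
  results <- lapply(k_range, function(k)
    consensus_cluster(V, k, n_runs = n_runs, seed = seed,
                      max_iter = max_iter, tol = tol))
  diag <- data.frame(k = k_range,
                     cophenetic = vapply(results, `[[`, 0, "cophenetic"),
                     mean_silhouette = vapply(results, `[[`, 0, "mean_silhouette"))
  top <- which(diag$cophenetic == max(diag$cophenetic))
  if (length(top) > 1)
    top <- top[diag$mean_silhouette[top] == max(diag$mean_silhouette[top])]
  best <- min(diag$k[top])
  list(best_k = best, diagnostics = diag,
       results = stats::setNames(results, paste0("k", k_range)))
}
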