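#' Joint latent-variable integrative clustering across omics layers
#'
#' Fits the stacked Gaussian latent-variable model `X_t = W_t Z + eps_t`
#' (latent dimension `k - 1`, `Z ~ N(0, I)`, diagonal layer noise `Psi_t`)
#' by EM with an elementwise lasso penalty `lambda` on the loadings. The
#' E-step is the closed-form posterior of `Z`; the penalized M-step for the
#' loadings is solved exactly by coordinate descent (which makes the
#' penalized observed-data objective provably non-decreasing across EM
#' iterations). Cluster labels come from seeded k-means on the latent
#' posterior means; the best of `n_init` random restarts by penalized
#' objective is returned.
#'
#' @param layers List of [omics_layer()] objects sharing the sample order.
#' @param k Number of clusters (latent dimension `k - 1`), `k >= 2`.
#' @param lambda Lasso penalty on the standardized scale (default 0.2).
#' @param n_init Random restarts (default 20).
#' @param seed Integer seed.
#' @param max_em_iter,tol EM stopping rule (relative objective change).
#' @param standardize Scale each feature to zero mean / unit variance first
#'   (default TRUE, the model's convention).
#' @return List of class `integrative_fit`: `k`, `lambda`, `W` (per layer),
#'   `psi` (per layer), `EZ` (n x (k-1) posterior means), `labels`,
#'   `objective_trace` of the best restart, `restart_objectives`,
#'   `restart_labels`, `degenerate` flag.
#' @export
icluster_fit <- function(layers, k, lambda = 0.2, n_init = 20, seed = 1,
                         max_em_iter = 200, tol = 1e-6, standardize = TRUE) {
  stopifnot(length(layers) >= 1, k >= 2)
  sids <- sample_ids(layers[[1]])
  for (l in layers)
    if (!identical(sample_ids(l), sids)) stop("layers must share the sample order")
  mats <- lapply(layers, function(l) l$values)
  if (standardize)
    mats <- lapply(mats, function(m) {
      sdv <- apply(m, 1, stats::sd)
      keep <- sdv > 0
      (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) / sdv[keep]
    })
  X <- do.call(rbind, mats)
  layer_rows <- rep(seq_along(mats), vapply(mats, nrow, 0L))
  p <- nrow(X); n <- ncol(X); d <- k - 1
  Sjj <- rowSums(X^2) / n
  const <- n * p * log(2 * pi)

  # spectral initialization: latent directions start aligned with the
  # dominant variance so informative loadings survive the lasso threshold;
  # restarts explore the basin via random rotations plus jitter
  sv <- svd(X, nu = d, nv = 0)
  W_base <- sv$u %*% diag(sv$d[seq_len(d)] / sqrt(n), d, d)
  jitter_sd <- 0.1 * stats::sd(W_base)

  set.seed(seed)
  init_seeds <- sample.int(.Machine$integer.max, n_init)
  best <- NULL
  restart_obj <- rep(NA_real_, n_init)
  restart_labels <- vector("list", n_init)
  for (s in seq_len(n_init)) {
    set.seed(init_seeds[s])
    rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    W <- W_base %*% rot + matrix(stats::rnorm(p * d, 0, jitter_sd), p, d)
    psi <- pmax(Sjj - rowSums(W^2), 0.1)
    trace <- numeric(0)
    prev <- -Inf
    fail <- FALSE
    for (it in seq_len(max_em_iter)) {
      Wpsi <- W / psi
      M <- diag(d) + crossprod(W, Wpsi)
      V <- solve(M)
      Tm <- crossprod(Wpsi, X)            # d x n, = W' Psi^-1 X
      # penalized observed-data log-likelihood at current parameters
      logdet <- sum(log(psi)) +
        as.numeric(determinant(M, logarithm = TRUE)$modulus)
      trS <- sum(Sjj / psi) - sum(V * tcrossprod(Tm)) / n
      obj <- -0.5 * (const + n * logdet + n * trS) - lambda * n * sum(abs(W))
      if (!is.finite(obj)) { fail <- TRUE; break }
      trace <- c(trace, obj)
      if (it > 1 && abs(obj - prev) <= tol * max(1, abs(prev))) break
      prev <- obj
      # E-step moments
      EZ <- V %*% Tm                      # d x n
      A <- n * V + tcrossprod(EZ)         # d x d, sum of E[z z']
      B <- X %*% t(EZ)                    # p x d, rows are sum_i E[z_i] x_ij
      # M-step: exact penalized update of W by coordinate descent, then psi
      for (sweep in 1:3) {
        for (l in seq_len(d)) {
          r <- B[, l] - W[, -l, drop = FALSE] %*% A[-l, l]
          thr <- lambda * n * psi
          W[, l] <- sign(r) * pmax(abs(r) - thr, 0) / A[l, l]
        }
      }
      q <- (2 * rowSums(W * B) - rowSums((W %*% A) * W)) / n
      psi <- pmax(Sjj - q, 1e-6)
    }
    if (fail || !length(trace)) next
    # labels from k-means on the latent posterior means
    Wpsi <- W / psi
    M <- diag(d) + crossprod(W, Wpsi)
    EZ <- solve(M, crossprod(Wpsi, X))
    degenerate <- max(abs(EZ)) < 1e-8
    labels <- if (degenerate) rep(1L, n) else {
      set.seed(init_seeds[s] %% 1000000L + 7L)
      km <- tryCatch(stats::kmeans(t(EZ), centers = k, nstart = 10),
                     error = function(e) NULL)
      if (is.null(km)) { degenerate <- TRUE; rep(1L, n) } else km$cluster
    }
    restart_obj[s] <- trace[length(trace)]
    restart_labels[[s]] <- labels
    if (is.null(best) || restart_obj[s] > best$objective) {
      best <- list(W = W, psi = psi, EZ = t(EZ), labels = labels,
                   objective = restart_obj[s], trace = trace,
                   degenerate = degenerate)
    }
  }
  if (is.null(best)) stop("icluster_fit(): all restarts failed")
  split_rows <- function(v) split(v, layer_rows)
  structure(list(k = k, lambda = lambda,
                 W = lapply(split(seq_len(p), layer_rows),
                            function(i) best$W[i, , drop = FALSE]),
                 psi = split_rows(best$psi),
                 EZ = best$EZ,
                 labels = stats::setNames(best$labels, sids),
                 objective = best$objective,
                 objective_trace = best$trace,
                 restart_objectives = restart_obj,
                 restart_labels = restart_labels,
                 degenerate = best$degenerate,
                 n_init = n_init, seed = seed),
            class = "integrative_fit")
}

#' Stability-based choice of the integrative cluster count
#'
#' For each `k`, fits [icluster_fit()] and scores the mean pairwise adjusted
#' Rand index of the restart labelings (stability) plus the best penalized
#' objective. The chosen `k` maximizes stability; exact ties go to the
#' higher objective.
#'
#' @inheritParams icluster_fit
#' @param k_range Candidate cluster counts (default 2:4).
#' @return List: `best_k`, `stability` (data.frame k / stability /
#'   objective), `fits`.
#' @export
choose_k_integrative <- function(layers, k_range = 2:4, lambda = 0.2,
                                 n_init = 20, seed = 1, max_em_iter = 200,
                                 tol = 1e-6) {
  fits <- lapply(k_range, function(k)
    icluster_fit(layers, k, lambda = lambda, n_init = n_init,
                 seed = seed, max_em_iter = max_em_iter, tol = tol))
  stab <- vapply(fits, function(f) {
    labs <- Filter(Negate(is.null), f$restart_labels)
    if (length(labs) < 2) return(1)
    pairs <- utils::combn(length(labs), 2)
    mean(apply(pairs, 2, function(ij)
      mclust::adjustedRandIndex(labs[[ij[1]]], labs[[ij[2]]])))
  }, 0)
  obj <- vapply(fits, `[[`, 0, "objective")
  tab <- data.frame(k = k_range, stability = stab, objective = obj)
  top <- which(stab == max(stab))
  if (length(top) > 1) top <- top[which.max(obj[top])]
  list(best_k = k_range[top], stability = tab,
       fits = stats::setNames(fits, paste0("k", k_range)))
}
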