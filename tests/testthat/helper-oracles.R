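# Independent oracles, written against the definitions rather than the
# package's code paths.

# Pearson correlation per row pair by the direct covariance formula.
naive_row_cor <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, ]; b <- y[i, ]
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    num / den
  }, 0)
}

# Two-group log-rank statistic by direct hypergeometric accumulation over
# event times (no ties assumed handled: d_j events at each distinct time).
logrank_oracle <- function(time, event, group) {
  stopifnot(all(group %in% c(1, 2)))
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V,
       chi2 = if (V > 0) (O - E)^2 / V else NA_real_)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration with the point-probability rule (probabilities within a
# 1 + 1e-7 relative tolerance of the observed one count as "as extreme",
# the standard convention).
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plain factor-analysis EM (no penalty, no Woodbury shortcuts): dense
# covariance log-likelihood, run to convergence from a spectral start.
fa_em_oracle <- function(X, d, max_iter = 10000, tol = 1e-13) {
  p <- nrow(X); n <- ncol(X)
  S <- tcrossprod(X) / n
  sv <- svd(X, nu = d, nv = 0)
  W <- sv$u %*% diag(sv$d[seq_len(d)] / sqrt(n), d, d)
  psi <- pmax(diag(S) - rowSums(W^2), 0.1)
  ll_of <- function(W, psi) {
    Sigma <- tcrossprod(W) + diag(psi)
    -0.5 * n * (p * log(2 * pi) +
                  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
                  sum(diag(solve(Sigma, S))))
  }
  prev <- NA_real_
  for (it in seq_len(max_iter)) {
    ll <- ll_of(W, psi)
    if (it > 1 && abs(ll - prev) <= tol * max(1, abs(prev))) break
    prev <- ll
    Minv <- solve(diag(d) + crossprod(W / psi, W))
    EZ <- Minv %*% crossprod(W / psi, X)
    A <- n * Minv + tcrossprod(EZ)
    B <- X %*% t(EZ)
    W <- B %*% solve(A)
    psi <- pmax(diag(S) - rowSums(W * B) / n, 1e-6)
  }
  list(W = W, psi = psi, loglik = ll_of(W, psi))
}

ari <- mclust::adjustedRandIndex
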