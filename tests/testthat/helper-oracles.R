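# Independent oracles and small fixture builders used across test files.

# Restricted log-likelihood evaluated by the literal formula with dense
# solve()/determinant() calls - an implementation path independent of the
# package's Cholesky-based engine.
naive_reml_loglik <- function(y, X, Klist, sigma2) {
  n <- length(y)
  C <- length(Klist)
  V <- diag(rep(sigma2[C + 1], n))
  for (c in seq_len(C)) V <- V + sigma2[c] * Klist[[c]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            drop(t(y) %*% P %*% y))
}

# Fast exact grid evaluation of the single-component restricted likelihood
# via the eigendecomposition of K (closed form, no iterative optimizer):
# returns the (sigma_g, sigma_e) grid point maximizing L_R.
grid_search_reml <- function(y, K, grid = seq(0, 1.5, by = 0.005)) {
  n <- length(y)
  e <- eigen(K, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, n)))
  best <- c(NA, NA); best_ll <- -Inf
  for (sg in grid) {
    vd <- outer(e$values, grid, function(d, se) sg * d + se)  # n x |grid|
    ok <- colSums(vd <= 1e-12) == 0
    if (!any(ok)) next
    vd <- vd[, ok, drop = FALSE]
    a <- colSums(xt^2 / vd)
    b <- colSums(xt * yt / vd)
    yPy <- colSums(yt^2 / vd) - b^2 / a
    ll <- -0.5 * (colSums(log(vd)) + log(a) + yPy)
    j <- which.max(ll)
    if (ll[j] > best_ll) {
      best_ll <- ll[j]
      best <- c(sg, grid[ok][j])
    }
  }
  list(sigma2 = best, loglik = best_ll)
}

# Naive double-loop IBS matrix: the textbook evaluation of the standardized
# genotype correlation, including the inbreeding-form diagonal.
naive_ibs <- function(counts, p) {
  n <- nrow(counts); m <- ncol(counts)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (i in seq_len(m)) {
        den <- 2 * p[i] * (1 - p[i])
        s <- s + if (j == k) {
          (counts[j, i]^2 - (1 + 2 * p[i]) * counts[j, i] + 2 * p[i]^2) / den
        } else {
          (counts[j, i] - 2 * p[i]) * (counts[k, i] - 2 * p[i]) / den
        }
      }
      A[j, k] <- if (j == k) 1 + s / m else s / m
    }
  }
  A
}

# Liability threshold and multiplier obtained by numerical integration of
# the normal threshold model (uniroot on the integrated upper-tail mass),
# independent of qnorm/dnorm-based closed forms.
integrate_liability_multiplier <- function(K) {
  phi <- function(x) exp(-x^2 / 2) / sqrt(2 * pi)
  tail_mass <- function(t)
    stats::integrate(phi, t, Inf, rel.tol = 1e-13, abs.tol = 1e-14)$value
  thr <- stats::uniroot(function(t) tail_mass(t) - K, c(-10, 10),
                        tol = 1e-12)$root
  z <- phi(thr)
  K * (1 - K) / z^2
}

# Random PSD kinship-like matrix with unit-ish diagonal.
random_psd_kinship <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(B) / (2 * n)
  K / mean(diag(K))
}

# Draw y from the single-component model y ~ N(0, sg*K + se*I).
draw_mvn_single <- function(K, sg, se, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(K)
  ch <- chol(sg * K + se * diag(n))
  drop(t(ch) %*% rnorm(n))
}

# Paired phenotypes with a given correlation (used by the pedigree-class
# tests): each row is one pair drawn from a standard bivariate normal.
draw_pairs <- function(n_pairs, rho) {
  z0 <- rnorm(n_pairs)
  a <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n_pairs)
  b <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n_pairs)
  cbind(a, b)
}
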