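#' Fit a variance-component mixed model by AI-REML
#'
#' Maximizes the restricted log-likelihood of the multivariate-normal model
#' \deqn{y \sim N(X\beta,\; V),\qquad
#'       V = \sum_c \sigma^2_c K_c + \sigma^2_e I,}
#' over the variance components \eqn{\sigma^2_c} (one per kinship matrix)
#' and the residual \eqn{\sigma^2_e}. The restricted log-likelihood is
#' \deqn{L_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right],\qquad
#'       P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}.}
#' The score for component c is
#' \eqn{-\tfrac12[\mathrm{tr}(PK_c) - y'PK_cPy]} and the average-information
#' matrix has entries \eqn{\tfrac12\, y'PK_cPK_dPy}. Updates are
#' average-information Newton steps with step-halving; when a step cannot be
#' accepted (log-likelihood decrease, bound violation, or loss of positive
#' definiteness) an EM-REML step is taken instead, which always increases
#' \eqn{L_R}. The first iteration is an EM step, which stabilizes poor
#' starting values. Convergence is declared when the relative change in
#' \eqn{L_R} falls below `tol`.
#'
#' Under the default non-negativity constraint, components driven below zero
#' are pinned at a small positive bound (`1e-6 * var(y)`), mirroring common
#' REML software; the unconstrained mode (needed for unbiased means and
#' well-calibrated boundary null distributions) allows negative estimates as
#' long as \eqn{V} stays positive definite.
#'
#' @param y numeric response vector (already covariate-aligned; [greml()] is
#'   the formula front end that prepares `y` and `X`).
#' @param X fixed-effect design matrix (including the intercept); must have
#'   full column rank.
#' @param K a list of [kinship_matrix()] objects or plain symmetric matrices,
#'   all in the same sample order as `y`.
#' @param constrain logical; constrain all variance components to be
#'   non-negative (default `TRUE`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of iterations; non-convergence flags the
#'   fit rather than raising an error.
#' @param start optional numeric vector of starting values (one per
#'   component plus the residual); defaults to `var(y) / (C + 1)` for each.
#' @param trace logical; print the iteration log.
#'
#' @return An object of class `reml_fit` with elements `sigma2` (named
#'   variance estimates, residual last), `se` (from the inverse
#'   average-information matrix), `vc_cov`, `loglik` (restricted), `loglik_trace`,
#'   `n_iter`, `converged`, `beta`, `beta_se`, `beta_cov`, `Py` and `n`.
#' @seealso [greml()], [h2_from_fit()], [lrt()]
#' @export
fit_reml <- function(y, X, K, constrain = TRUE, tol = 1e-6, max_iter = 100L,
                     start = NULL, trace = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (qr(X)$rank < ncol(X)) stop("X does not have full column rank")
  if (inherits(K, "kinship_matrix") || is.matrix(K)) K <- list(K)
  Kmats <- lapply(K, function(k) if (inherits(k, "kinship_matrix")) k$values else as.matrix(k))
  C <- length(Kmats)
  if (C == 0) stop("at least one kinship component is required")
  for (k in Kmats) if (!all(dim(k) == n)) stop("kinship dimensions must match length(y)")
  knames <- names(K)
  if (is.null(knames) || any(knames == ""))
    knames <- paste0("K", seq_len(C))
  pn <- c(knames, "residual")
  if (n < C + 1 + ncol(X) + 2)
    stop("too few samples: need n >= ", C + 1 + ncol(X) + 2)

  vp <- stats::var(y)
  if (!is.finite(vp) || vp <= 0) stop("response has no variance")
  lb <- 1e-6 * vp
  theta <- if (is.null(start)) rep(vp / (C + 1), C + 1) else as.numeric(start)
  if (length(theta) != C + 1) stop("start must have ", C + 1, " elements")
  if (constrain) theta <- pmax(theta, lb)

  parts_at <- function(th) .reml_parts(y, X, Kmats, th)
  derivs_at <- function(parts) .reml_derivs(parts, Kmats)

  parts <- parts_at(theta)
  if (is.null(parts))
    stop("covariance matrix not positive definite at the starting values")
  ll_trace <- parts$ll
  converged <- FALSE
  iter <- 0L
  rel_prev <- Inf

  em_step <- function(theta, d) {
    theta + theta^2 * (d$yPKPy - d$trPK) / n
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    d <- derivs_at(parts)
    accepted <- FALSE
    if (iter > 1L) {
      # Newton direction from the AI matrix; under the constraint,
      # components pushed below the bound are pinned there (active set)
      # and the step is re-solved over the free components.
      propose <- function(step) {
        delta <- tryCatch(solve(d$AI, d$score), error = function(e) NULL)
        if (is.null(delta)) return(NULL)
        cand <- theta + step * delta
        if (constrain && any(cand < lb)) {
          free <- seq_along(theta)
          for (pass in seq_along(theta)) {
            act <- which(cand < lb)
            if (length(act) == 0) break
            free <- setdiff(free, act)
            cand[act] <- lb
            if (length(free) == 0) break
            delta_f <- tryCatch(
              solve(d$AI[free, free, drop = FALSE], d$score[free]),
              error = function(e) NULL)
            if (is.null(delta_f)) return(NULL)
            cand[free] <- theta[free] + step * delta_f
          }
          cand[cand < lb] <- lb
        }
        cand
      }
      step <- 1
      for (h in 1:10) {
        cand <- propose(step)
        if (!is.null(cand)) {
          p2 <- parts_at(cand)
          if (!is.null(p2) && p2$ll >= parts$ll - 1e-10) {
            theta <- cand; parts <- p2; accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
    }
    if (!accepted) {                     # EM fallback (and first iteration)
      cand <- em_step(theta, d)
      if (constrain) cand <- pmax(cand, lb)
      p2 <- parts_at(cand)
      if (is.null(p2))
        stop("covariance matrix lost positive definiteness at iteration ",
             iter, "; log-likelihood trace: ",
             paste(sprintf("%.4f", ll_trace), collapse = ", "))
      theta <- cand; parts <- p2
    }
    ll_trace <- c(ll_trace, parts$ll)
    if (trace)
      message(sprintf("iter %2d  logLik %.6f  sigma2 = %s", iter, parts$ll,
                      paste(sprintf("%.5f", theta), collapse = " ")))
    rel <- abs(ll_trace[iter + 1] - ll_trace[iter]) /
      (abs(ll_trace[iter]) + 1e-10)
    # require two consecutive sub-tolerance changes so that a slow EM crawl
    # along a constraint boundary is not mistaken for convergence
    if (rel < tol && rel_prev < tol) { converged <- TRUE; break }
    rel_prev <- rel
  }

  d <- derivs_at(parts)
  vc_cov <- tryCatch(solve(d$AI), error = function(e) ginv_sym(d$AI))
  se <- sqrt(pmax(diag(vc_cov), 0))
  beta <- drop(parts$W %*% y)
  beta_cov <- tryCatch(solve(parts$XtViX), error = function(e) ginv_sym(parts$XtViX))
  names(beta) <- colnames(X)
  dimnames(vc_cov) <- list(pn, pn)
  names(theta) <- names(se) <- pn

  structure(
    list(sigma2 = theta, se = se, vc_cov = vc_cov,
         loglik = parts$ll, loglik_trace = ll_trace,
         n_iter = iter, converged = converged,
         beta = beta, beta_se = sqrt(pmax(diag(beta_cov), 0)),
         beta_cov = beta_cov, Py = parts$Py,
         n = n, constrain = constrain,
         pinned = if (constrain) theta <= lb * (1 + 1e-8) else rep(FALSE, C + 1)),
    class = "reml_fit"
  )
}

# Restricted-likelihood building blocks at a parameter point theta
# (components first, residual last). Returns NULL if V or X'V^-1 X loses
# positive definiteness.
.reml_parts <- function(y, X, Kmats, th) {
  n <- length(y)
  C <- length(Kmats)
  V <- diag(rep(th[C + 1], n))
  for (c in seq_len(C)) V <- V + th[c] * Kmats[[c]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cXX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXX)) return(NULL)
  W <- chol2inv(cXX) %*% t(ViX)          # (X'V^-1 X)^-1 X'V^-1
  P <- Vi - ViX %*% W
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cXX))) +
                  sum(y * Py))
  list(P = P, Py = Py, ll = ll, W = W, XtViX = XtViX, y = y)
}

# Score vector and average-information matrix given .reml_parts() output.
.reml_derivs <- function(parts, Kmats) {
  C <- length(Kmats)
  P <- parts$P; Py <- parts$Py
  q <- vector("list", C + 1)
  trPK <- numeric(C + 1)
  yPKPy <- numeric(C + 1)
  for (c in seq_len(C)) {
    q[[c]] <- drop(Kmats[[c]] %*% Py)
    trPK[c] <- sum(P * Kmats[[c]])       # tr(P K), K symmetric
    yPKPy[c] <- sum(Py * q[[c]])
  }
  q[[C + 1]] <- Py
  trPK[C + 1] <- sum(diag(P))
  yPKPy[C + 1] <- sum(Py * Py)
  score <- -0.5 * (trPK - yPKPy)
  Pq <- lapply(q, function(v) drop(P %*% v))
  AI <- matrix(0, C + 1, C + 1)
  for (a in seq_len(C + 1))
    for (b in a:(C + 1))
      AI[a, b] <- AI[b, a] <- 0.5 * sum(q[[a]] * Pq[[b]])
  list(score = score, AI = AI, trPK = trPK, yPKPy = yPKPy)
}

#' Evaluate the restricted likelihood, score and average information
#'
#' Computes the restricted log-likelihood \eqn{L_R}, its analytic score
#' vector (one entry per variance component, residual last) and the
#' average-information matrix at a given parameter point, without
#' iterating. Useful for diagnostics and for checking the optimizer
#' against numerical derivatives.
#'
#' @inheritParams fit_reml
#' @param sigma2 parameter point: variance components in the order of `K`,
#'   residual variance last.
#' @return A list with `loglik`, `score` and `AI`.
#' @export
reml_deriv <- function(y, X, K, sigma2) {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1)
  if (inherits(K, "kinship_matrix") || is.matrix(K)) K <- list(K)
  Kmats <- lapply(K, function(k) if (inherits(k, "kinship_matrix")) k$values else as.matrix(k))
  if (length(sigma2) != length(Kmats) + 1)
    stop("sigma2 must have one entry per component plus the residual")
  parts <- .reml_parts(y, as.matrix(X), Kmats, as.numeric(sigma2))
  if (is.null(parts)) stop("V is not positive definite at this point")
  d <- .reml_derivs(parts, Kmats)
  list(loglik = parts$ll, score = d$score, AI = d$AI)
}

# Moore-Penrose inverse for a symmetric matrix (used when the AI matrix is
# singular, e.g. with components pinned at the bound).
ginv_sym <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values), 1)
  inv <- ifelse(pos, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

#' Variance proportions (heritability components) from a REML fit
#'
#' Converts the variance components of a [fit_reml()] / [greml()] fit to
#' proportions of total phenotypic variance,
#' \eqn{h^2_c = \sigma^2_c / (\sum_d \sigma^2_d + \sigma^2_e)}, with
#' standard errors by the delta method using the full covariance matrix of
#' the variance estimates.
#'
#' @param fit a `reml_fit` object.
#' @return A data frame with one row per variance parameter (residual last)
#'   and columns `component`, `sigma2`, `proportion`, `se`.
#' @export
h2_from_fit <- function(fit) {
  if (!inherits(fit, "reml_fit")) stop("fit must be a reml_fit")
  if (!isTRUE(fit$converged))
    warning("REML fit did not converge; proportions may be unreliable")
  th <- fit$sigma2
  S <- sum(th)
  if (S <= 0) stop("total fitted variance is not positive")
  prop <- th / S
  m <- length(th)
  se <- vapply(seq_len(m), function(c) {
    g <- -th[c] / S^2
    g <- rep(g, m)
    g[c] <- (S - th[c]) / S^2
    sqrt(max(0, drop(t(g) %*% fit$vc_cov %*% g)))
  }, numeric(1))
  data.frame(component = names(th), sigma2 = unname(th),
             proportion = unname(prop), se = unname(se),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Computes \eqn{\Lambda = 2(L_{full} - L_{null})}, clamped at zero, and the
#' upper-tail chi-square p-value with `df` degrees of freedom. Both fits
#' must use the same response, fixed effects and (for the null) a strict
#' subset of the full model's kinship components; REML log-likelihoods are
#' only comparable when the fixed-effect design is identical.
#'
#' When a variance component is tested on the boundary of its parameter
#' space the plain chi-square reference is conservative; the
#' `boundary = "mixture"` option uses the \eqn{\tfrac12\chi^2_0 +
#' \tfrac12\chi^2_1} mixture instead (only meaningful for `df = 1`).
#'
#' @param fit_full,fit_null `reml_fit` objects for the full and null models.
#' @param df degrees of freedom (number of extra variance components).
#' @param boundary `"chisq"` (default) for the plain reference, `"mixture"`
#'   for the 50:50 boundary mixture.
#' @return A list with `statistic`, `df`, `p_value` and `boundary`.
#' @export
lrt <- function(fit_full, fit_null, df = 1L, boundary = c("chisq", "mixture")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(fit_full, "reml_fit"), inherits(fit_null, "reml_fit"))
  if (fit_full$n != fit_null$n)
    stop("fits use different numbers of samples")
  lam <- 2 * (fit_full$loglik - fit_null$loglik)
  # a constrained full model pinned at the boundary ties the null to within
  # rounding; only a deficit large relative to the log-likelihood scale
  # indicates an optimizer failure
  if (lam < -1e-6 * (1 + abs(fit_null$loglik)))
    warning("full-model log-likelihood is below the null's (",
            sprintf("%.3g", lam / 2), "); the optimizer likely failed - refit")
  lam <- max(0, lam)
  p <- stats::pchisq(lam, df = df, lower.tail = FALSE)
  if (boundary == "mixture")
    p <- if (lam == 0) 1 else 0.5 * stats::pchisq(lam, df = df, lower.tail = FALSE)
  list(statistic = lam, df = df, p_value = p, boundary = boundary)
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML variance-component fit (",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  cat("  restricted logLik:", format(x$loglik, digits = digits + 2), "\n")
  tab <- data.frame(sigma2 = x$sigma2, se = x$se)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  h2 <- h2_from_fit(object)
  structure(list(fit = object, h2 = h2), class = "summary.reml_fit")
}

#' @export
print.summary.reml_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nVariance proportions:\n")
  print(cbind(x$h2[1], round(x$h2[-1], digits)))
  cat("\nFixed effects:\n")
  fe <- data.frame(estimate = x$fit$beta, se = x$fit$beta_se)
  print(round(fe, digits))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2) + length(object$beta),
            class = "logLik")
}

#' @export
vcov.reml_fit <- function(object, what = c("fixed", "varcomp"), ...) {
  what <- match.arg(what)
  if (what == "fixed") object$beta_cov else object$vc_cov
}
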