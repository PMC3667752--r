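#' Fit a genomic REML (GREML) mixed model
#'
#' The main fitting interface of the package. Fits the linear mixed model
#' \deqn{y = X\beta + \sum_c g_c + e,\qquad
#'       g_c \sim N(0, \sigma^2_c K_c),\quad e \sim N(0, \sigma^2_e I)}
#' by restricted maximum likelihood ([fit_reml()]), where each \eqn{K_c} is
#' a [kinship_matrix()] (IBS, thresholded IBS, IBD or IBD2). The proportion
#' of phenotypic variance on each kinship component is the corresponding
#' heritability parameter: with a single IBD matrix it estimates total
#' narrow-sense heritability; with a single (centered) IBS matrix on
#' unrelated samples it estimates the heritability tagged by genotyped SNPs.
#'
#' Samples are matched between `data` and the kinship matrices by
#' identifier, never by position: rows of `data` lacking a kinship entry
#' (or with missing model variables) are dropped, and the fit is run in the
#' order the remaining identifiers appear in `data`.
#'
#' Quantitative responses are standardized to mean 0, variance 1 before
#' fitting (so variance components are proportions of phenotypic variance);
#' dichotomous 0/1 responses are left on the observed scale, to be converted
#' to the liability scale downstream (see [observed_to_liability()]).
#'
#' @param formula model formula, e.g. `height ~ age + sex + region`; the
#'   right-hand side defines the fixed effects (factors are one-hot encoded
#'   with a reference level, as usual in R).
#' @param data data frame containing the response, the covariates and an
#'   identifier column.
#' @param kinship a [kinship_matrix()] or (possibly named) list of them.
#' @param id_col name of the identifier column in `data`.
#' @param normalize `"auto"` (standardize quantitative, leave 0/1 traits),
#'   `TRUE` (always standardize) or `FALSE` (never).
#' @param constrain,tol,max_iter,start passed to [fit_reml()].
#'
#' @return An object of class `c("greml", "reml_fit")`; see [fit_reml()] for
#'   the shared fields. Adds `ids`, `y`, `X`, `kinship` (the aligned list),
#'   `kinds`, `normalized`, `formula` and `call`. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `residuals`, `predict` (BLUP),
#'   `simulate`, `plot` and `anova` (likelihood-ratio test between nested
#'   fits).
#'
#' @examples
#' set.seed(1)
#' sim <- simulate_cohort(simulation_spec(
#'   pair_blocks = list(c(50, 0.5)), m_observed = 300, m_unobserved = 300,
#'   seed = 1))
#' K <- build_ibd(sim$true_ibd, sim$phenotype$id)
#' fit <- greml(trait ~ 1, data = sim$phenotype, kinship = list(ibd = K))
#' summary(fit)
#' @export
greml <- function(formula, data, kinship, id_col = "id",
                  normalize = "auto", constrain = TRUE, tol = 1e-6,
                  max_iter = 100L, start = NULL) {
  if (inherits(kinship, "kinship_matrix")) kinship <- list(kinship)
  if (!is.list(kinship) || !all(vapply(kinship, inherits, TRUE, "kinship_matrix")))
    stop("kinship must be a kinship_matrix or a list of them")
  if (!id_col %in% colnames(data)) stop("no '", id_col, "' column in data")
  ids_data <- as.character(data[[id_col]])
  if (anyDuplicated(ids_data)) stop("duplicated sample identifiers in data")

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  ids <- ids_data[keep]
  for (K in kinship) ids <- ids[ids %in% K$sample_ids]
  if (length(ids) < 10) stop("fewer than 10 samples after alignment")
  rows <- match(ids, ids_data)
  mf <- mf[rows, , drop = FALSE]

  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  dichot <- all(y %in% c(0, 1))
  do_norm <- identical(normalize, TRUE) ||
    (identical(normalize, "auto") && !dichot)
  if (do_norm) y <- (y - mean(y)) / stats::sd(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  Ks <- lapply(kinship, subset_kinship, ids = ids)
  Kv <- lapply(Ks, function(k) k$values)
  names(Kv) <- names(kinship)

  # duplicated component matrices cannot be separated
  if (length(Kv) > 1) {
    for (a in seq_len(length(Kv) - 1))
      for (b in (a + 1):length(Kv))
        if (max(abs(Kv[[a]] - Kv[[b]])) < 1e-10)
          stop("kinship components ", a, " and ", b,
               " are identical; the variance split is not identifiable")
  }

  fit <- fit_reml(y, X, Kv, constrain = constrain, tol = tol,
                  max_iter = max_iter, start = start)
  fit$ids <- ids
  fit$y <- y
  fit$X <- X
  fit$kinship <- Ks
  fit$kinds <- vapply(Ks, function(k) k$kind, character(1))
  fit$dichotomous <- dichot
  fit$normalized <- do_norm
  fit$formula <- formula
  fit$call <- match.call()
  class(fit) <- c("greml", "reml_fit")
  fit
}

#' @export
print.greml <- function(x, digits = 4, ...) {
  cat("GREML fit:", deparse(x$formula), "\n")
  cat("  kinship components:", paste(x$kinds, collapse = " + "), "\n")
  cat("  n =", x$n, if (x$dichotomous) " (dichotomous trait, observed scale)",
      "\n")
  NextMethod()
}

#' @export
residuals.greml <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$y - drop(object$X %*% object$beta)
  if (type == "conditional") {
    for (c in seq_along(object$kinship))
      r <- r - object$sigma2[c] * drop(object$kinship[[c]]$values %*% object$Py)
  }
  r
}

#' Predict from a GREML fit
#'
#' `type = "blup"` (default) returns the conditional mean
#' \eqn{X\beta + \sum_c \hat g_c} with the best linear unbiased predictions
#' \eqn{\hat g_c = \sigma^2_c K_c P y} of the random genetic values;
#' `type = "fixed"` returns the fixed-effect mean only.
#'
#' @param object a [greml()] fit.
#' @param type `"blup"` or `"fixed"`.
#' @param ... unused.
#' @return Named numeric vector over the fitted samples.
#' @export
predict.greml <- function(object, type = c("blup", "fixed"), ...) {
  type <- match.arg(type)
  mu <- drop(object$X %*% object$beta)
  if (type == "blup")
    for (c in seq_along(object$kinship))
      mu <- mu + object$sigma2[c] * drop(object$kinship[[c]]$values %*% object$Py)
  stats::setNames(mu, object$ids)
}

#' @export
simulate.greml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  V <- diag(rep(object$sigma2[length(object$sigma2)], n))
  for (c in seq_along(object$kinship))
    V <- V + object$sigma2[c] * object$kinship[[c]]$values
  ch <- chol(V)
  mu <- drop(object$X %*% object$beta)
  out <- as.data.frame(
    mu + t(ch) %*% matrix(stats::rnorm(n * nsim), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$ids
  out
}

#' @export
plot.greml <- function(x, ...) {
  graphics::plot(seq_along(x$loglik_trace) - 1, x$loglik_trace,
                 type = "b", xlab = "iteration",
                 ylab = "restricted log-likelihood",
                 main = "AI-REML convergence", ...)
  invisible(x)
}

#' Likelihood-ratio comparison of nested GREML fits
#'
#' @param object the null (smaller) model.
#' @param ... exactly one larger model whose kinship components are a strict
#'   superset of the null's, fitted to the same response and fixed effects.
#' @param boundary passed to [lrt()].
#' @return A data frame LRT table; the p-value is from [lrt()] with
#'   `df` equal to the difference in the number of variance components.
#' @export
anova.greml <- function(object, ..., boundary = "chisq") {
  others <- list(...)
  others <- Filter(function(o) inherits(o, "reml_fit"), others)
  if (length(others) != 1)
    stop("anova.greml() compares exactly two nested fits")
  full <- others[[1]]
  if (length(full$sigma2) <= length(object$sigma2)) {
    tmp <- full; full <- object; object <- tmp
  }
  df <- length(full$sigma2) - length(object$sigma2)
  res <- lrt(full, object, df = df, boundary = boundary)
  data.frame(
    model = c("null", "full"),
    n_varcomp = c(length(object$sigma2), length(full$sigma2)),
    logLik = c(object$loglik, full$loglik),
    statistic = c(NA, res$statistic),
    df = c(NA, res$df),
    p_value = c(NA, res$p_value)
  )
}
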