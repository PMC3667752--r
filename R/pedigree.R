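#' Expected genome sharing for the named relationship classes
#'
#' Returns the seven standard relative classes with the fraction of the
#' genome expected to be shared IBD (single-chromosome sharing weighted 1/2)
#' and the expected IBD2 fraction (both chromosomes shared). Maternal and
#' paternal half-siblings are pooled in one class.
#'
#' @return A data frame with columns `class`, `expected_ibd`,
#'   `expected_ibd2`.
#' @export
relationship_classes <- function() {
  data.frame(
    class = c("MZ-twin", "sibling", "parent-offspring", "half-sibling",
              "grandparent-grandchild", "avuncular", "first-cousin"),
    expected_ibd = c(1, 0.5, 0.5, 0.25, 0.25, 0.25, 0.125),
    expected_ibd2 = c(1, 0.25, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

.class_expected_ibd <- function(cls) {
  rc <- relationship_classes()
  if (is.character(cls)) {
    i <- match(cls, rc$class)
    if (is.na(i)) stop("unknown relationship class '", cls, "'; one of: ",
                       paste(rc$class, collapse = ", "))
    rc$expected_ibd[i]
  } else if (is.numeric(cls)) {
    if (cls <= 0 || cls > 1) stop("expected IBD fraction must be in (0, 1]")
    cls
  } else stop("cls must be a class name or an expected IBD fraction")
}

#' Correlation-based heritability estimate for one relationship class
#'
#' Estimates heritability as the Pearson phenotype correlation across pairs
#' of one relationship class divided by the class's expected IBD fraction
#' (e.g. times 2 for siblings or parent-offspring pairs, times 8 for first
#' cousins). Each pair enters the correlation once in each order, so the
#' estimate is invariant to which member is listed first. No standard error
#' is attached: pairs within a class are themselves related in complex ways,
#' so independent-sampling errors would be wrong; aggregate across traits
#' instead ([class_average()], [compare_classes()]).
#'
#' Phenotypes should be residualized for covariates beforehand
#' ([residualize()]).
#'
#' @param pairs two-column numeric matrix or data frame; each row holds the
#'   phenotype values of one pair.
#' @param cls relationship class name (see [relationship_classes()]) or an
#'   expected IBD fraction in (0, 1].
#' @param min_pairs emit a warning below this many pairs (study-design
#'   filter, not an estimator property).
#' @return The heritability estimate (can exceed 1, with a warning, when the
#'   pair correlation exceeds the expected sharing).
#' @export
class_h2 <- function(pairs, cls, min_pairs = 2) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have exactly two columns")
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 2) stop("need at least 2 complete pairs")
  if (nrow(pairs) < min_pairs)
    warning("only ", nrow(pairs), " pairs (< ", min_pairs, ")")
  if (stats::sd(pairs[, 1]) == 0 || stats::sd(pairs[, 2]) == 0)
    stop("zero phenotype variance in a member position; correlation undefined")
  a <- c(pairs[, 1], pairs[, 2])
  b <- c(pairs[, 2], pairs[, 1])
  r <- stats::cor(a, b)
  est <- r / .class_expected_ibd(cls)
  if (est > 1)
    warning("class estimate ", sprintf("%.3f", est),
            " exceeds 1 (pair correlation above expected sharing)")
  est
}

#' Residualize a phenotype on fixed-effect covariates
#'
#' Linear-model residuals used to pre-adjust phenotypes before the
#' correlation-based class estimators.
#'
#' @param formula e.g. `trait ~ age + sex + region`.
#' @param data data frame.
#' @return Numeric residuals, `NA` for rows with missing model variables.
#' @export
residualize <- function(formula, data) {
  fit <- stats::lm(formula, data = data, na.action = stats::na.exclude)
  stats::resid(fit)
}

#' Compare two relationship classes across traits
#'
#' Takes per-trait heritability estimates for two classes, forms the
#' per-trait differences, and tests the mean difference with a Wald test:
#' s.e. = sd(differences) / sqrt(number of traits), two-sided normal
#' p-value. This is how classes with equal expected IBD (e.g. half-siblings
#' vs grandparent-grandchild) are compared to detect shared-environment or
#' non-additive inflation.
#'
#' @param est_a,est_b named numeric vectors of per-trait estimates; the
#'   trait sets must match.
#' @return A list with `mean_diff`, `se`, `statistic`, `p_value`,
#'   `n_traits`.
#' @export
compare_classes <- function(est_a, est_b) {
  if (is.null(names(est_a)) || is.null(names(est_b)))
    stop("estimates must be named by trait")
  if (!setequal(names(est_a), names(est_b)))
    stop("trait sets differ between the two classes")
  est_b <- est_b[names(est_a)]
  d <- est_a - est_b
  nt <- length(d)
  if (nt < 2) stop("need at least 2 traits")
  m <- mean(d)
  se <- stats::sd(d) / sqrt(nt)
  if (se == 0) {
    if (m == 0) {
      p <- 1; z <- 0
    } else {
      warning("zero variance of differences; p-value below machine precision")
      p <- .Machine$double.xmin
      z <- sign(m) * Inf
    }
  } else {
    z <- m / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(mean_diff = m, se = se, statistic = z, p_value = p, n_traits = nt)
}

#' Cross-trait average heritability per relationship class
#'
#' For each class, the mean across traits and a normal-approximation 95%
#' confidence interval for that mean (empirical sd / sqrt(n traits)).
#'
#' @param estimates data frame or matrix, traits in rows, classes in
#'   columns, of per-trait class heritability estimates.
#' @return A data frame with columns `class`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`, `n_traits`.
#' @export
class_average <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop("need at least 2 traits per class")
  z <- stats::qnorm(0.975)
  m <- colMeans(estimates, na.rm = TRUE)
  s <- apply(estimates, 2, stats::sd, na.rm = TRUE)
  nt <- colSums(!is.na(estimates))
  se <- s / sqrt(nt)
  data.frame(class = colnames(estimates), mean = unname(m), sd = unname(s),
             ci_lo = unname(m - z * se), ci_hi = unname(m + z * se),
             n_traits = unname(nt), stringsAsFactors = FALSE)
}
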