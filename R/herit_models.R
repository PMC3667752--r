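#' Heritability report container
#'
#' Common return value of the named estimators [estimate_h2()],
#' [estimate_joint()] and [fit_ade()]. Fields not applicable to a model are
#' `NA`.
#'
#' @param model one of `"IBD"`, `"IBS"`, `"IBS_THR"`, `"JOINT_THR_IBS"`,
#'   `"JOINT_IBD_IBS"`, `"ADE"`.
#' @param h2_total,h2_total_se total narrow-sense heritability and s.e.
#' @param h2_g,h2_g_se heritability explained by genotyped SNPs and s.e.
#' @param h2_dominance_like,h2_dominance_like_se the combined shared-
#'   environment/dominance/epistasis component (on IBD2) and s.e.
#' @param ratio_h2g_over_h2,ratio_se the ratio h2_g / h2_total and its
#'   delta-method s.e.
#' @param scale `"observed"` or `"liability"`.
#' @param lrt_p likelihood-ratio p-value (ADE model only).
#' @param liability_upper_bound logical flag: liability-scale totals from
#'   family-based components cannot be fully corrected for relative
#'   ascertainment and are upper bounds.
#' @param prevalence,case_fraction population prevalence and in-sample case
#'   fraction used for the liability conversion.
#' @param fit,fit_null underlying [greml()] fits.
#' @return An object of class `heritability_report`.
#' @export
heritability_report <- function(model, h2_total, h2_total_se,
                                h2_g = NA_real_, h2_g_se = NA_real_,
                                h2_dominance_like = NA_real_,
                                h2_dominance_like_se = NA_real_,
                                ratio_h2g_over_h2 = NA_real_,
                                ratio_se = NA_real_,
                                scale = "observed", lrt_p = NA_real_,
                                liability_upper_bound = FALSE,
                                prevalence = NA_real_,
                                case_fraction = NA_real_,
                                fit = NULL, fit_null = NULL) {
  structure(
    list(model = model, h2_total = h2_total, h2_total_se = h2_total_se,
         h2_g = h2_g, h2_g_se = h2_g_se,
         h2_dominance_like = h2_dominance_like,
         h2_dominance_like_se = h2_dominance_like_se,
         ratio_h2g_over_h2 = ratio_h2g_over_h2, ratio_se = ratio_se,
         scale = scale, lrt_p = lrt_p,
         liability_upper_bound = liability_upper_bound,
         prevalence = prevalence, case_fraction = case_fraction,
         fit = fit, fit_null = fit_null),
    class = "heritability_report"
  )
}

#' @export
print.heritability_report <- function(x, digits = 3, ...) {
  f <- function(v, s) if (is.na(v)) "-" else
    sprintf("%.*f (s.e. %.*f)", digits, v, digits, s)
  cat("Heritability report [", x$model, "], ", x$scale, " scale",
      if (isTRUE(x$liability_upper_bound)) " (total: upper bound)", "\n",
      sep = "")
  cat("  h2 total:          ", f(x$h2_total, x$h2_total_se), "\n")
  if (!is.na(x$h2_g))
    cat("  h2 genotyped SNPs: ", f(x$h2_g, x$h2_g_se), "\n")
  if (!is.na(x$h2_dominance_like))
    cat("  dominance-like:    ", f(x$h2_dominance_like,
                                   x$h2_dominance_like_se), "\n")
  if (!is.na(x$ratio_h2g_over_h2))
    cat("  h2_g / h2:         ", f(x$ratio_h2g_over_h2, x$ratio_se), "\n")
  if (!is.na(x$lrt_p))
    cat("  LRT p (dominance-like = 0):", format.pval(x$lrt_p, digits), "\n")
  invisible(x)
}

# center an IBS-type matrix unless already centered; IBD-types pass through
.prep_kinship <- function(K) {
  if (K$kind %in% c("IBS", "IBS_THRESHOLDED") && !isTRUE(K$centered))
    center_ibs(K) else K
}

#' Single-component heritability estimate
#'
#' Fits a one-kinship GREML model and reports the genetic variance
#' proportion. With an IBD matrix this estimates total narrow-sense
#' heritability; with a thresholded IBS matrix it is the phase-free
#' approximation to it; with a raw IBS matrix on data containing relatives
#' the estimate lies between the SNP heritability and the total (and is
#' reported as model `"IBS"`). IBS-type matrices are mean-centered before
#' fitting; IBD-type matrices are used as-is.
#'
#' @param formula model formula (trait ~ covariates).
#' @param data data frame with an `id` column (see [greml()]).
#' @param K a [kinship_matrix()] of kind IBD, IBS or IBS_THRESHOLDED.
#' @param prevalence for dichotomous traits, the population prevalence used
#'   to convert to the liability scale; `NULL` leaves the observed scale.
#' @param ... passed to [greml()].
#' @return A [heritability_report()].
#' @export
estimate_h2 <- function(formula, data, K, prevalence = NULL, ...) {
  if (!inherits(K, "kinship_matrix")) stop("K must be a kinship_matrix")
  if (K$kind == "IBD2") stop("IBD2 matrices enter through fit_ade(), not estimate_h2()")
  model <- switch(K$kind, IBD = "IBD", IBS = "IBS",
                  IBS_THRESHOLDED = "IBS_THR")
  fit <- greml(formula, data, kinship = list(g = .prep_kinship(K)), ...)
  h2 <- h2_from_fit(fit)
  rep <- heritability_report(model, h2$proportion[1], h2$se[1], fit = fit)
  .maybe_liability(rep, fit, prevalence)
}

#' Joint estimation of total and SNP heritability
#'
#' Fits the two-kinship GREML model with a "close-relative" matrix (the
#' thresholded IBS matrix, or an IBD matrix) and the full IBS matrix. The
#' parameter on the full IBS matrix is the heritability explained by
#' genotyped SNPs (h2_g); the total narrow-sense heritability is the sum of
#' the two genetic proportions. This decomposition estimates both
#' quantities without removing related individuals.
#'
#' @param formula,data,prevalence,... as in [estimate_h2()].
#' @param K_close [kinship_matrix()] of kind `"IBS_THRESHOLDED"` or `"IBD"`.
#' @param K_ibs [kinship_matrix()] of kind `"IBS"` (unthresholded).
#' @return A [heritability_report()] with `h2_total`, `h2_g` and their ratio.
#' @export
estimate_joint <- function(formula, data, K_close, K_ibs, prevalence = NULL,
                           ...) {
  if (!inherits(K_close, "kinship_matrix") || !inherits(K_ibs, "kinship_matrix"))
    stop("K_close and K_ibs must be kinship_matrix objects")
  if (!K_close$kind %in% c("IBS_THRESHOLDED", "IBD"))
    stop("K_close must be of kind IBS_THRESHOLDED or IBD, not ", K_close$kind)
  if (K_ibs$kind != "IBS")
    stop("K_ibs must be of kind IBS, not ", K_ibs$kind)
  model <- if (K_close$kind == "IBD") "JOINT_IBD_IBS" else "JOINT_THR_IBS"
  fit <- greml(formula, data,
               kinship = list(close = .prep_kinship(K_close),
                              ibs = .prep_kinship(K_ibs)), ...)
  th <- fit$sigma2            # (close, ibs, residual)
  S <- sum(th)
  h2_close <- th[1] / S; h2_g <- th[2] / S
  h2_tot <- h2_close + h2_g
  Vc <- fit$vc_cov
  # delta method: gradients of the proportions in (theta1, theta2, theta_e)
  g_tot <- c(th[3], th[3], -(th[1] + th[2])) / S^2
  se_tot <- sqrt(max(0, drop(t(g_tot) %*% Vc %*% g_tot)))
  g_g <- c(-th[2], S - th[2], -th[2]) / S^2
  se_g <- sqrt(max(0, drop(t(g_g) %*% Vc %*% g_g)))
  ratio <- if (h2_tot > 0) h2_g / h2_tot else NA_real_
  se_r <- if (h2_tot > 0) {
    gr <- c(-th[2], th[1], 0) / (th[1] + th[2])^2
    sqrt(max(0, drop(t(gr) %*% Vc %*% gr)))
  } else NA_real_
  rep <- heritability_report(model, unname(h2_tot), se_tot,
                             h2_g = unname(h2_g), h2_g_se = se_g,
                             ratio_h2g_over_h2 = unname(ratio),
                             ratio_se = unname(se_r), fit = fit)
  .maybe_liability(rep, fit, prevalence)
}

#' Fit the ADE model (additive + dominance-like components)
#'
#' Fits the two-component model with the IBD and IBD2 kinship matrices. The
#' parameter on IBD is the narrow-sense heritability; the parameter on IBD2
#' captures the combined effect of shared environment, dominance and
#' epistasis ("dominance-like"), since all three load on pairs that share
#' both chromosomes. A one-degree-of-freedom likelihood-ratio test against
#' the IBD-only model tests whether the dominance-like component is zero.
#'
#' When no pair has a positive IBD2 fraction the component is not
#' identifiable; it is pinned at zero with a warning and no test is run.
#'
#' @param formula,data,... as in [estimate_h2()].
#' @param K_ibd [kinship_matrix()] of kind `"IBD"`.
#' @param K_ibd2 [kinship_matrix()] of kind `"IBD2"`.
#' @param boundary reference distribution for the LRT, see [lrt()].
#' @return A [heritability_report()] with `h2_total` (the additive part),
#'   `h2_dominance_like` and `lrt_p`.
#' @export
fit_ade <- function(formula, data, K_ibd, K_ibd2, boundary = "chisq", ...) {
  if (!inherits(K_ibd, "kinship_matrix") || K_ibd$kind != "IBD")
    stop("K_ibd must be a kinship_matrix of kind IBD")
  if (!inherits(K_ibd2, "kinship_matrix") || K_ibd2$kind != "IBD2")
    stop("K_ibd2 must be a kinship_matrix of kind IBD2")
  fit_null <- greml(formula, data, kinship = list(ibd = K_ibd), ...)
  off <- K_ibd2$values[upper.tri(K_ibd2$values)]
  if (!any(off > 0)) {
    warning("no pair shares both chromosomes (all IBD2 entries are 0); ",
            "the dominance-like component is not identifiable and is pinned at 0")
    h2 <- h2_from_fit(fit_null)
    return(heritability_report("ADE", h2$proportion[1], h2$se[1],
                               h2_dominance_like = 0,
                               h2_dominance_like_se = NA_real_,
                               fit = fit_null, fit_null = fit_null))
  }
  fit <- greml(formula, data, kinship = list(ibd = K_ibd, ibd2 = K_ibd2), ...)
  h2 <- h2_from_fit(fit)
  test <- lrt(fit, fit_null, df = 1L, boundary = boundary)
  heritability_report("ADE", h2$proportion[1], h2$se[1],
                      h2_dominance_like = h2$proportion[2],
                      h2_dominance_like_se = h2$se[2],
                      lrt_p = test$p_value, fit = fit, fit_null = fit_null)
}

#' Convert observed-scale heritability to the liability scale
#'
#' For a dichotomous trait analyzed as 0/1 on the observed scale, the
#' liability-scale heritability under the normal threshold model with
#' case-control ascertainment is
#' \deqn{h^2_l = h^2_o \cdot \frac{K(1-K)}{z^2} \cdot \frac{K(1-K)}{P(1-P)},}
#' where \eqn{K} is the population prevalence, \eqn{P} the fraction of cases
#' in the analyzed sample, and \eqn{z = \phi(\Phi^{-1}(1-K))} the standard
#' normal density at the liability threshold. With \eqn{P = K} (no
#' ascertainment) this reduces to the classical \eqn{K(1-K)/z^2} conversion.
#'
#' @param h2_obs observed-scale heritability; a negative value (possible
#'   under unconstrained REML) is converted with a warning.
#' @param prevalence population prevalence \eqn{K}, in (0, 1).
#' @param case_fraction in-sample case fraction \eqn{P}, in (0, 1); defaults
#'   to `prevalence` (no ascertainment correction).
#' @return Liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, prevalence,
                                  case_fraction = prevalence) {
  if (!is.numeric(prevalence) || any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly between 0 and 1")
  if (!is.numeric(case_fraction) || any(case_fraction <= 0 | case_fraction >= 1))
    stop("case_fraction must lie strictly between 0 and 1")
  if (any(h2_obs < 0, na.rm = TRUE))
    warning("negative observed-scale heritability converted as-is")
  K <- prevalence; P <- case_fraction
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_obs * (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
}

#' Estimate the prevalence of a dichotomous trait
#'
#' The fraction of cases among non-missing 0/1 phenotype values.
#'
#' @param pheno numeric vector of 0/1 values (`NA` allowed).
#' @return Cases / (cases + controls).
#' @export
estimate_prevalence <- function(pheno) {
  pheno <- pheno[!is.na(pheno)]
  if (length(pheno) == 0) stop("all phenotype values are missing")
  if (!all(pheno %in% c(0, 1)))
    stop("phenotype is not dichotomous (values other than 0/1)")
  ncase <- sum(pheno == 1)
  if (ncase == 0 || ncase == length(pheno))
    stop("need at least one case and one control")
  ncase / length(pheno)
}

# Apply the liability conversion to a report when the trait is dichotomous
# and a prevalence is supplied. The SNP component h2_g receives the full
# ascertainment correction (in-sample case fraction); family-based totals
# can only receive the unascertained conversion and are flagged as upper
# bounds, since no correction exists for ascertainment of affected
# relatives.
.maybe_liability <- function(rep, fit, prevalence) {
  if (is.null(prevalence)) return(rep)
  if (!isTRUE(fit$dichotomous)) {
    warning("prevalence supplied for a quantitative trait; ignored")
    return(rep)
  }
  P <- mean(fit$y)
  mult_plain <- observed_to_liability(1, prevalence)
  mult_full <- observed_to_liability(1, prevalence, P)
  rep$h2_total <- rep$h2_total * mult_plain
  rep$h2_total_se <- rep$h2_total_se * mult_plain
  if (!is.na(rep$h2_g)) {
    rep$h2_g <- rep$h2_g * mult_full
    rep$h2_g_se <- rep$h2_g_se * mult_full
  }
  if (!is.na(rep$h2_dominance_like)) {
    rep$h2_dominance_like <- rep$h2_dominance_like * mult_plain
    rep$h2_dominance_like_se <- rep$h2_dominance_like_se * mult_plain
  }
  rep$scale <- "liability"
  rep$liability_upper_bound <- TRUE
  rep$prevalence <- prevalence
  rep$case_fraction <- P
  rep
}
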