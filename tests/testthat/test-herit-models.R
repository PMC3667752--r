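test_that("liability conversion matches its closed form and edge cases", {
  expect_equal(observed_to_liability(0, 0.1, 0.3), 0)
  # K = P = 0.5: multiplier 0.25 / dnorm(0)^2 = pi/2
  expect_equal(observed_to_liability(0.2, 0.5), 0.2 * pi / 2)
  expect_equal(observed_to_liability(0.2, 0.5), 0.31416, tolerance = 1e-4)
  expect_error(observed_to_liability(0.5, 0), "prevalence")
  expect_error(observed_to_liability(0.5, 0.1, 1), "case_fraction")
  expect_warning(observed_to_liability(-0.1, 0.1), "negative")
})

test_that("liability conversion agrees with numeric integration of the threshold model", {
  for (K in c(0.01, 0.1, 0.3, 0.5)) {
    mult <- integrate_liability_multiplier(K)
    expect_equal(observed_to_liability(1, K), mult, tolerance = 1e-6)
  }
})

test_that("liability conversion is monotone in h2 and continuous in K and P", {
  h <- seq(0, 1, by = 0.05)
  out <- observed_to_liability(h, 0.07, 0.2)
  expect_true(all(diff(out) > 0))
  # continuity: vanishing steps in K or P change the result proportionally
  Ks <- seq(0.02, 0.6, by = 0.001)
  outK <- vapply(Ks, function(K) observed_to_liability(0.3, K), numeric(1))
  expect_true(all(abs(diff(outK)) / outK[-1] < 0.05))
  Ps <- seq(0.05, 0.95, by = 0.001)
  outP <- vapply(Ps, function(P) observed_to_liability(0.3, 0.1, P), numeric(1))
  expect_true(all(abs(diff(outP)) / outP[-1] < 0.05))
})

test_that("prevalence estimation counts cases among non-missing", {
  expect_equal(estimate_prevalence(c(rep(1, 419), rep(0, 10085))),
               419 / 10504)
  expect_equal(round(estimate_prevalence(c(rep(1, 419), rep(0, 10085))), 4),
               0.0399)
  expect_equal(estimate_prevalence(c(1, 0, NA)), 0.5)
  expect_error(estimate_prevalence(c(1, 1)), "control")
  expect_error(estimate_prevalence(c(NA_real_, NA_real_)), "missing")
})

test_that("single-component estimator is unbiased at zero for pure noise", {
  # heritability 0 cohorts; unconstrained fits so the mean can straddle 0
  ests <- vapply(1:25, function(r) {
    sim <- simulate_cohort(simulation_spec(
      pair_blocks = list(c(150, 0.5)), m_observed = 400, m_unobserved = 0,
      h2_observed = 0, h2_unobserved = 0, seed = 500 + r))
    K <- build_ibd(sim$true_ibd, sim$phenotype$id)
    estimate_h2(trait ~ 1, sim$phenotype, K, constrain = FALSE)$h2_total
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * mc_se)
})

test_that("joint model attributes everything to SNPs when nothing is hidden", {
  diffs <- vapply(1:6, function(r) {
    sim <- simulate_cohort(simulation_spec(
      pair_blocks = list(c(300, 0.5)), m_observed = 2000, m_unobserved = 0,
      h2_observed = 0.5, h2_unobserved = 0, seed = 600 + r))
    K_ibs <- build_ibs(sim$observed)
    rep <- estimate_joint(trait ~ 1, sim$phenotype,
                          threshold_ibs(K_ibs, 0.05), K_ibs,
                          constrain = FALSE)
    rep$h2_total - rep$h2_g
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), max(3 * mc_se, 0.02))
})

test_that("covariate fixed effects are absorbed before variance estimation", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(250, 0.5)), m_observed = 1000, m_unobserved = 1000,
    seed = 77))
  ph <- sim$phenotype
  # inject strong age/sex effects; adjusting must recover the same h2
  ph$trait2 <- ph$trait + 0.05 * ph$age + 2 * (ph$sex == "M")
  K <- build_ibd(sim$true_ibd, ph$id)
  h_adj <- estimate_h2(trait2 ~ age + sex + region, ph, K)$h2_total
  h_ref <- estimate_h2(trait ~ 1, ph, K)$h2_total
  expect_equal(h_adj, h_ref, tolerance = 0.05)
})

test_that("ADE model pins the dominance-like term when IBD2 is uninformative", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(100, 0.5, 0)),  # parent-offspring style: no IBD2
    m_observed = 400, m_unobserved = 0, h2_observed = 0.4,
    h2_unobserved = 0, seed = 800))
  K_ibd <- build_ibd(sim$true_ibd, sim$phenotype$id)
  K_ibd2 <- build_ibd2(sim$true_ibd, sim$phenotype$id)
  expect_warning(
    rep <- fit_ade(trait ~ 1, sim$phenotype, K_ibd, K_ibd2),
    "not identifiable")
  expect_equal(rep$h2_dominance_like, 0)
  expect_true(is.na(rep$lrt_p))
})

test_that("ADE decomposition respects the unit total under the constraint", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(100, 0.5, 0.25), c(100, 0.5, 0)),
    m_observed = 600, m_unobserved = 600, seed = 810))
  K_ibd <- build_ibd(sim$true_ibd, sim$phenotype$id)
  K_ibd2 <- build_ibd2(sim$true_ibd, sim$phenotype$id)
  rep <- fit_ade(trait ~ 1, sim$phenotype, K_ibd, K_ibd2)
  expect_gte(rep$h2_total, 0)
  expect_gte(rep$h2_dominance_like, 0)
  expect_lte(rep$h2_total + rep$h2_dominance_like, 1 + 1e-8)
  expect_true(rep$lrt_p >= 0 && rep$lrt_p <= 1)
})

test_that("a shared pair environment loads on the dominance-like component", {
  # sib-like plus parent-offspring pairs separate additive from IBD2 signal;
  # a dominance-like variance of 0.3 (share 0.3/1.3) must be recovered
  # without bias and be detectable in aggregate. Per-replicate LRT power at
  # this contrast is low by design (the sib-vs-parent-offspring covariance
  # difference is only 0.25 * sigma2_d), so no per-replicate rejection rate
  # is asserted.
  det <- t(vapply(1:20, function(r) {
    sim <- simulate_cohort(simulation_spec(
      pair_blocks = list(c(100, 0.5, 0.25), c(100, 0.5, 0)),
      m_observed = 600, m_unobserved = 600, seed = 900 + r,
      shared_pair_var = 0.3))
    K_ibd <- build_ibd(sim$true_ibd, sim$phenotype$id)
    K_ibd2 <- build_ibd2(sim$true_ibd, sim$phenotype$id)
    # unconstrained: the bounded fit truncates the (very dispersed) null
    # tail at 0 and would bias the replicate mean upward
    rep <- fit_ade(trait ~ 1, sim$phenotype, K_ibd, K_ibd2,
                   constrain = FALSE)
    c(d = rep$h2_dominance_like, p = rep$lrt_p)
  }, c(d = 0, p = 0)))
  mc_se <- sd(det[, "d"]) / sqrt(nrow(det))
  # mean dominance-like share significantly above zero ...
  expect_gt(mean(det[, "d"]) / mc_se, 3)
  # ... and consistent with the generative share 0.3 / 1.3
  expect_lt(abs(mean(det[, "d"]) - 0.3 / 1.3), 3 * mc_se)
})

test_that("liability conversion is applied per component with ascertainment", {
  set.seed(42)
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(250, 0.5)), m_observed = 800, m_unobserved = 800,
    seed = 1000))
  ph <- sim$phenotype
  # dichotomize at the 80th percentile -> case fraction 0.2 in-sample
  ph$cc <- as.numeric(ph$trait > quantile(ph$trait, 0.8))
  K <- build_ibd(sim$true_ibd, ph$id)
  rep_obs <- estimate_h2(cc ~ 1, ph, K)
  rep_liab <- estimate_h2(cc ~ 1, ph, K, prevalence = 0.1)
  expect_equal(rep_obs$scale, "observed")
  expect_equal(rep_liab$scale, "liability")
  expect_true(rep_liab$liability_upper_bound)
  mult <- observed_to_liability(1, 0.1)
  expect_equal(rep_liab$h2_total, rep_obs$h2_total * mult)
  # h2_g in a joint fit gets the full case-fraction correction
  K_ibs <- build_ibs(sim$observed)
  rj <- estimate_joint(cc ~ 1, ph, threshold_ibs(K_ibs, 0.05), K_ibs,
                       prevalence = 0.1)
  P <- mean(ph$cc)
  expect_equal(rj$h2_g / (rj$fit$sigma2[2] / sum(rj$fit$sigma2)),
               observed_to_liability(1, 0.1, P),
               tolerance = 1e-8, ignore_attr = TRUE)
})
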