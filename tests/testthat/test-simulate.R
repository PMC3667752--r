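test_that("the same seed reproduces the cohort exactly", {
  spec <- simulation_spec(pair_blocks = list(c(40, 0.5)), m_observed = 300,
                          m_unobserved = 300, seed = 11)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1$observed$counts, s2$observed$counts)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$true_ibd$pairs, s2$true_ibd$pairs)
  s3 <- simulate_cohort(simulation_spec(pair_blocks = list(c(40, 0.5)),
                                        m_observed = 300, m_unobserved = 300,
                                        seed = 12))
  expect_false(identical(s1$phenotype$trait, s3$phenotype$trait))
})

test_that("spec validation rejects infeasible worlds", {
  expect_error(simulation_spec(pair_blocks = list(c(10, 1.2))), "ibd fraction")
  expect_error(simulation_spec(pair_blocks = list(c(10, 0.2, 0.3))), "ibd2")
  expect_error(simulation_spec(h2_observed = 0.6, h2_unobserved = 0.5),
               "noise")
  expect_error(simulation_spec(maf_range = c(0, 0.5)), "maf_range")
})

test_that("fully-IBD pairs have identical genotypes and IBS near 1", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(50, 1)), m_observed = 1500, m_unobserved = 0,
    h2_observed = 0.4, h2_unobserved = 0, seed = 21))
  a <- seq(1, 99, 2); b <- seq(2, 100, 2)
  expect_identical(unname(sim$observed$counts[a, ]),
                   unname(sim$observed$counts[b, ]))
  K <- build_ibs(sim$observed)
  expect_equal(mean(K$values[cbind(a, b)]), 1, tolerance = 0.05)
  expect_equal(sim$true_ibd$pairs$ibd, rep(1, 50))
})

test_that("phenotype variance is near 1 with the stated genetic share", {
  sim <- simulate_cohort(simulation_spec(seed = 31))  # full default design
  expect_equal(var(sim$phenotype$trait), 1, tolerance = 0.1)
  g <- sim$genetic_values$observed + sim$genetic_values$unobserved
  # realized genetic variance within 5% of h2_obs + h2_unobs = 0.5
  expect_equal(var(g), 0.5, tolerance = 0.05)
  expect_equal(var(sim$genetic_values$observed), 0.25, tolerance = 0.05)
  expect_equal(sim$true_params$h2_total, 0.5)
  expect_equal(sim$true_params$h2_g, 0.25)
  # per-SNP effect at the defaults is sqrt(0.5/10000) on each panel
  expect_equal(sqrt(sim$spec$h2_observed / sim$spec$m_observed),
               sqrt(0.5 / 10000))
  # realized allele frequencies track the drawn ones at n = 1400
  dev <- abs(sim$observed$freqs - sim$maf[seq_len(sim$spec$m_observed)])
  expect_gte(mean(dev < 0.05), 0.99)
})

test_that("one-haplotype copy mode halves the realized relatedness", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(200, 0.5)), m_observed = 2500, m_unobserved = 0,
    h2_observed = 0.4, h2_unobserved = 0, seed = 41, copy_mode = "one"))
  expect_equal(sim$true_ibd$pairs$ibd, rep(0.25, 200))
  expect_equal(sim$true_ibd$pairs$ibd2, rep(0, 200))
  K <- build_ibs(sim$observed)
  n <- nrow(K$values)
  offs <- K$values[cbind(seq(1, n - 1, 2), seq(2, n, 2))]
  mc_se <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - 0.25), 3 * mc_se)
})

test_that("split-chromosome phenotypes report exact realized truths", {
  set.seed(51)
  counts <- matrix(rbinom(300 * 40, 2, 0.3), 300, 40)
  G <- genotype_matrix(counts, map = data.frame(chrom = rep(1:4, each = 10)))
  # spacing larger than any parity set -> one causal SNP per parity
  res <- split_chromosome_phenotype(G, spacing = 40, alpha1 = 0.3,
                                    alpha2 = 0.2, noise1 = 0.4, noise2 = 0.3,
                                    seed = 5)
  expect_length(res$C1, 1)
  expect_length(res$C2, 1)
  vg1 <- var(counts[, res$C1] * 0.3)
  vg2 <- var(counts[, res$C2] * 0.2)
  expect_equal(res$true_params$h2_g, vg1 / (vg1 + vg2 + 0.7))
  expect_equal(res$true_params$h2_total, (vg1 + vg2) / (vg1 + vg2 + 0.7))
  # C1 sits on even chromosomes, C2 on odd
  expect_true(all(G$map$chrom[res$C1] %% 2 == 0))
  expect_true(all(G$map$chrom[res$C2] %% 2 == 1))

  # nothing on the odd side -> everything genotyped
  res2 <- split_chromosome_phenotype(G, spacing = 5, alpha1 = 0.3,
                                     alpha2 = 0, noise2 = 0, noise1 = 0.5,
                                     seed = 6)
  expect_equal(res2$true_params$h2_g, res2$true_params$h2_total)
})

test_that("split-chromosome parameter recovery on even-chromosome GRMs", {
  # scaled-down analogue of the real-genotype validation: phenotype from
  # both parities, GRM from even chromosomes only, joint fit recovers truth
  ests <- t(vapply(1:8, function(r) {
    sim <- simulate_cohort(simulation_spec(
      pair_blocks = list(c(300, 0.5)), m_observed = 2000, m_unobserved = 0,
      h2_observed = 0.4, h2_unobserved = 0, seed = 700 + r))
    G <- sim$observed
    G$map <- data.frame(chrom = rep(1:4, length.out = 2000))
    sp <- split_chromosome_phenotype(G, spacing = 2, alpha1 = 0.032,
                                     alpha2 = 0.032, noise1 = 0.25,
                                     noise2 = 0.25, seed = 700 + r)
    even <- which(G$map$chrom %% 2 == 0)
    Ge <- genotype_matrix(G$counts[, even], sample_ids = G$sample_ids)
    K_ibs <- build_ibs(Ge)
    ph <- sp$phenotype
    rep <- estimate_joint(trait ~ 1, ph, threshold_ibs(K_ibs, 0.05), K_ibs,
                          constrain = FALSE)
    c(h2 = rep$h2_total - sp$true_params$h2_total,
      h2g = rep$h2_g - sp$true_params$h2_g)
  }, c(h2 = 0, h2g = 0)))
  for (col in c("h2", "h2g")) {
    mc_se <- sd(ests[, col]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, col])), 3 * mc_se)
  }
})

test_that("replicate_study is deterministic and summarizes per estimator", {
  spec <- simulation_spec(pair_blocks = list(c(60, 0.5)), m_observed = 400,
                          m_unobserved = 400, seed = 61)
  r1 <- replicate_study(spec, 2, estimators = c("ibd", "joint_thr"))
  r2 <- replicate_study(spec, 2, estimators = c("ibd", "joint_thr"))
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(nrow(r1$replicates), 4)
  expect_equal(sort(unique(r1$replicates$estimator)), c("ibd", "joint_thr"))
  expect_true(all(c("mean_h2_total", "sd_h2_total") %in% colnames(r1$summary)))
})
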