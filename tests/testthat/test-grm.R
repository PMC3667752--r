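test_that("IBS entries match the hand-evaluated standardized correlation", {
  # one SNP, counts (2, 0) -> in-sample p = 0.5; off-diagonal
  # (2 - 1)(0 - 1) / (2 * 0.5 * 0.5) = -2
  G <- genotype_matrix(matrix(c(2L, 0L), 2, 1))
  K <- build_ibs(G)
  expect_equal(K$kind, "IBS")
  expect_equal(K$values[1, 2], -2)
  # diagonal: 1 + (4 - 2*2 + 0.5)/0.5 = 2 for x = 2; same for x = 0
  expect_equal(unname(diag(K$values)), c(2, 2))
})

test_that("IBS matrix equals the naive double-loop evaluation", {
  set.seed(33)
  p_true <- runif(12, 0.2, 0.8)
  counts <- sapply(p_true, function(p) rbinom(8, 2, p))
  # guard against monomorphic draws at n = 8
  counts[1, colMeans(counts) %in% c(0, 2)] <- 1L
  G <- genotype_matrix(counts)
  K <- build_ibs(G)
  expect_equal(unname(K$values), naive_ibs(G$counts, G$freqs),
               tolerance = 1e-12)
})

test_that("degenerate SNPs are rejected by name; all-missing rows score zero", {
  G <- genotype_matrix(matrix(c(0L, 0L, 1L, 0L), 2, 2,
                              dimnames = list(NULL, c("mono", "poly"))))
  expect_error(build_ibs(G), "mono")
  # a sample with all genotypes missing is imputed to 2p -> centered score 0
  counts <- rbind(matrix(rep(c(0L, 1L, 2L), 4), 4, 3), NA_integer_)
  K <- build_ibs(genotype_matrix(counts))
  expect_equal(unname(K$values[5, 1:4]), rep(0, 4))
})

test_that("thresholding zeroes entries at or below t and never the diagonal", {
  V <- diag(c(1.02, 1.02, 1.02))
  V[1, 2] <- V[2, 1] <- 0.04
  V[1, 3] <- V[3, 1] <- 0.05
  V[2, 3] <- V[3, 2] <- 0.06
  K <- kinship_matrix(V, kind = "IBS")
  Kt <- threshold_ibs(K, 0.05)
  expect_equal(Kt$kind, "IBS_THRESHOLDED")
  expect_equal(Kt$threshold, 0.05)
  expect_equal(Kt$values[1, 2], 0)
  expect_equal(Kt$values[1, 3], 0)   # boundary: <= t is zeroed
  expect_equal(Kt$values[2, 3], 0.06)
  expect_equal(unname(diag(Kt$values)), rep(1.02, 3))
  # idempotent
  expect_equal(threshold_ibs(Kt, 0.05)$values, Kt$values)
  # t = 0 keeps all-positive off-diagonals
  Kp <- kinship_matrix(matrix(c(1, .2, .2, 1), 2), kind = "IBS")
  expect_equal(threshold_ibs(Kp, 0)$values[1, 2], 0.2)
  expect_error(threshold_ibs(Kp, -0.1), "non-negative")
})

test_that("centering zeroes the off-diagonal mean, keeps differences and diagonal", {
  set.seed(5)
  V <- random_psd_kinship(6) + 0.1
  diag(V) <- diag(V) + 0.5
  K <- kinship_matrix(V, kind = "IBS")
  Kc <- center_ibs(K)
  off <- row(Kc$values) != col(Kc$values)
  expect_lt(abs(mean(Kc$values[off])), 1e-12)
  expect_equal(diag(Kc$values), diag(K$values))
  # pairwise differences preserved exactly
  expect_equal(Kc$values[1, 2] - Kc$values[3, 4],
               K$values[1, 2] - K$values[3, 4])
  # all-equal off-diagonals center to zero
  Ke <- kinship_matrix(matrix(0.1, 3, 3) + diag(0.9, 3), kind = "IBS")
  expect_equal(unname(center_ibs(Ke)$values[1, 2]), 0)
  # idempotent no-op, with a message
  expect_message(Kc2 <- center_ibs(Kc), "already centered")
  expect_equal(Kc2$values, Kc$values)
  # IBD matrices are never centered
  Ki <- kinship_matrix(diag(3), kind = "IBD")
  expect_error(center_ibs(Ki), "not centered")
})

test_that("IBD/IBD2 matrices follow the diagonal and sharing conventions", {
  tab <- ibd_table(data.frame(
    id_a = c("s1", "p1", "s1"), id_b = c("s2", "o1", "s1"),
    ibd = c(0.5, 0.5, 0.05), ibd2 = c(0.25, 0, 0)))
  ids <- c("s1", "s2", "p1", "o1", "x")
  K <- build_ibd(tab, ids)
  expect_equal(K$kind, "IBD")
  expect_equal(K$values["s1", "s2"], 0.5)
  expect_equal(K$values["s1", "s1"], 1.05)  # self-record adds to the diagonal
  expect_equal(K$values["s2", "s2"], 1)
  expect_equal(K$values["x", "p1"], 0)

  K2 <- build_ibd2(tab, ids)
  expect_equal(K2$kind, "IBD2")
  expect_equal(K2$values["s1", "s2"], 0.25)  # sibling expectation
  expect_equal(K2$values["p1", "o1"], 0)     # parent-offspring shares one copy
  expect_equal(unname(diag(K2$values)), rep(1, 5))  # diagonal fixed at 1

  # empty table -> identity
  expect_equal(unname(build_ibd(ibd_table(), c("a", "b", "c"))$values), diag(3))
})

test_that("IBS off-diagonals are unbiased for the imposed pairwise IBD", {
  # 350 pairs at IBD 0.25: the mean standardized-IBS entry across pairs
  # must sit within 3 MC standard errors of 0.25
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(350, 0.25)), m_observed = 2000, m_unobserved = 0,
    h2_observed = 0.4, h2_unobserved = 0, seed = 91))
  K <- build_ibs(sim$observed)
  n <- nrow(K$values)
  offs <- K$values[cbind(seq(1, n - 1, 2), seq(2, n, 2))]
  mc_se <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - 0.25), 3 * mc_se)
})

test_that("IBS and true IBD agree in expectation for parent-offspring pairs", {
  # one haplotype fully shared: ibd = 0.5, ibd2 = 0; at 5000 SNPs the mean
  # IBS entry must be within 0.01 of the IBD value
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(300, 0.5, 0)), m_observed = 5000, m_unobserved = 0,
    h2_observed = 0.4, h2_unobserved = 0, seed = 92))
  K <- build_ibs(sim$observed)
  n <- nrow(K$values)
  offs <- K$values[cbind(seq(1, n - 1, 2), seq(2, n, 2))]
  expect_lt(abs(mean(offs) - 0.5), 0.01)
})

test_that("pruning removes all pairs above the cutoff and nothing else", {
  sim <- simulate_cohort(simulation_spec(
    pair_blocks = list(c(30, 0.5)), m_observed = 2000, m_unobserved = 0,
    h2_observed = 0.4, h2_unobserved = 0, seed = 93))
  K <- build_ibs(sim$observed)
  keep <- prune_related(K, 0.1)
  # one member of each imposed pair must go, none of the unrelated ones
  expect_equal(length(keep), 30)
  Vs <- subset_kinship(K, keep)$values
  diag(Vs) <- 0
  expect_true(all(Vs <= 0.1))
})
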