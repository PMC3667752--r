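#' Specification for a simulated cohort
#'
#' Describes the stated world of the genotype-and-phenotype simulator: a set
#' of pair blocks imposing pairwise IBD structure, observed and unobserved
#' SNP panels, a uniform allele-frequency range, and an additive variance
#' split. The defaults reproduce the reference design: 700 pairs at 50%
#' IBD, 5,000 observed + 5,000 unobserved SNPs with frequencies drawn
#' uniformly from (0.05, 0.5), per-SNP effect `sqrt(0.5/10000)` on
#' standardized genotypes (heritability 0.25 from each SNP set) and noise
#' variance 0.5, giving a phenotype with mean 0, variance 1 and
#' heritability 50%, half of it due to observed genotypes.
#'
#' @param pair_blocks list of numeric vectors `c(n_pairs, ibd)` or
#'   `c(n_pairs, ibd, ibd2)`. By default `ibd2 = ibd`: both haplotypes are
#'   copied at the selected positions, so the IBS expectation for the pair
#'   equals `ibd`. Supplying `ibd2 < ibd` makes the simulator copy both
#'   haplotypes over a fraction `ibd2` of the genome and a single haplotype
#'   over a disjoint fraction `2*(ibd - ibd2)` (half-weighted sharing), so
#'   that the IBD-weighted sharing is still `ibd`; sib-like pairs are
#'   `c(n, 0.5, 0.25)`.
#' @param m_observed,m_unobserved number of SNPs in the observed (genotyping
#'   platform) and unobserved panels.
#' @param maf_range allele-frequency range for the uniform draw.
#' @param h2_observed,h2_unobserved variance contributed by each panel; the
#'   noise variance is `1 - h2_observed - h2_unobserved` and must be
#'   positive.
#' @param seed integer seed; all randomness flows from it.
#' @param copy_mode `"both"` (default) copies both haplotypes at the
#'   selected positions; `"one"` copies only the first haplotype over a
#'   fraction `ibd` of positions, which halves the realized relatedness
#'   (recorded as `ibd/2` in the truth table, IBD2 = 0).
#' @param block_copy copy contiguous position blocks instead of an
#'   independent uniform subset (IBD-segment realism).
#' @param shared_pair_var variance of a dominance-like effect drawn from
#'   `N(0, shared_pair_var * K_IBD2)`: every individual receives it, and
#'   members of a pair share it in proportion to their IBD2 fraction (used
#'   to create shared-environment/dominance signal); default 0.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(pair_blocks = list(c(700, 0.5)),
                            m_observed = 5000, m_unobserved = 5000,
                            maf_range = c(0.05, 0.5),
                            h2_observed = 0.25, h2_unobserved = 0.25,
                            seed = 1L, copy_mode = c("both", "one"),
                            block_copy = FALSE, shared_pair_var = 0) {
  copy_mode <- match.arg(copy_mode)
  if (!is.list(pair_blocks)) pair_blocks <- list(pair_blocks)
  blocks <- lapply(pair_blocks, function(b) {
    b <- as.numeric(b)
    if (length(b) == 2) b <- c(b, b[2])
    if (length(b) != 3) stop("pair block must be c(n_pairs, ibd[, ibd2])")
    if (b[1] < 1 || b[1] != round(b[1])) stop("n_pairs must be a positive integer")
    if (b[2] < 0 || b[2] > 1) stop("ibd fraction must lie in [0, 1]")
    if (b[3] < 0 || b[3] > b[2]) stop("ibd2 must lie in [0, ibd]")
    u <- 2 * (b[2] - b[3])
    if (u + b[3] > 1 + 1e-12)
      stop("infeasible block: one-haplotype fraction 2*(ibd - ibd2) plus ",
           "ibd2 exceeds 1")
    stats::setNames(b, c("n_pairs", "ibd", "ibd2"))
  })
  if (m_observed < 1 || m_unobserved < 0) stop("invalid SNP counts")
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high < 1")
  if (h2_observed < 0 || h2_unobserved < 0 ||
      h2_observed + h2_unobserved >= 1)
    stop("need h2_observed + h2_unobserved < 1 (the remainder is noise)")
  seed <- as.integer(seed)
  structure(
    list(pair_blocks = blocks, m_observed = as.integer(m_observed),
         m_unobserved = as.integer(m_unobserved), maf_range = maf_range,
         h2_observed = h2_observed, h2_unobserved = h2_unobserved,
         seed = seed, copy_mode = copy_mode, block_copy = block_copy,
         shared_pair_var = shared_pair_var),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("simulation_spec: ",
      paste(vapply(x$pair_blocks, function(b)
        sprintf("%dx(ibd %.3g, ibd2 %.3g)", b[1], b[2], b[3]), ""),
        collapse = " + "), "\n", sep = "")
  cat("  SNPs:", x$m_observed, "observed +", x$m_unobserved, "unobserved;",
      "maf ~ U(", x$maf_range[1], ",", x$maf_range[2], ")\n")
  cat("  h2: observed", x$h2_observed, "+ unobserved", x$h2_unobserved,
      "; noise var", 1 - x$h2_observed - x$h2_unobserved, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# column-standardize with realized sample moments; monomorphic columns give
# a zero (not NaN) contribution to the genetic value
.standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(X^2) - mu^2) * sqrt(nrow(X) / (nrow(X) - 1))
  s[s == 0] <- Inf
  t((t(X) - mu) / s)
}

#' Simulate a cohort with imposed pairwise IBD structure
#'
#' Draws two binary haplotypes per individual per SNP (Bernoulli with the
#' SNP's allele frequency) for an observed and an unobserved panel. For each
#' pair in a block, haplotypes of the first member are copied onto the
#' second at a uniformly chosen subset of positions spanning the whole
#' genome (both panels), realizing the block's IBD/IBD2 fractions exactly
#' (up to floor rounding). The phenotype is additive over all SNPs:
#' standardized genotypes times per-SNP effects `sqrt(h2_k / m_k)` for panel
#' k, plus normal noise with variance `1 - h2_observed - h2_unobserved`.
#'
#' @param spec a [simulation_spec()].
#' @param keep_haplotypes attach the haplotype matrices to the returned
#'   genotype objects (memory-heavy; default `FALSE`).
#' @return An object of class `simulated_cohort`: a list with `observed` and
#'   `unobserved` [genotype_matrix()] objects, `true_ibd` ([ibd_table()]),
#'   `phenotype` (data frame with `id`, `trait` and inert `age`, `sex`,
#'   `region` covariate columns), `true_params` (`h2_total`, `h2_g`),
#'   `genetic_values` (the realized genetic value of each individual per
#'   panel) and `maf` (the drawn allele frequencies, observed panel first).
#' @export
simulate_cohort <- function(spec, keep_haplotypes = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n_pairs <- sum(vapply(spec$pair_blocks, `[`, numeric(1), 1))
  n <- 2L * as.integer(n_pairs)
  m <- spec$m_observed + spec$m_unobserved
  ids <- sprintf("I%05d", seq_len(n))

  p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  H1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  H2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)

  pick <- function(k) {
    if (k == 0) return(integer(0))
    if (spec$block_copy) {
      s <- sample.int(m - k + 1L, 1L)
      s:(s + k - 1L)
    } else sample.int(m, k)
  }

  pair_rows <- vector("list", n_pairs)
  idx <- 0L
  for (b in spec$pair_blocks) {
    for (r in seq_len(b["n_pairs"])) {
      idx <- idx + 1L
      a <- 2L * idx - 1L; bb <- 2L * idx
      if (spec$copy_mode == "one") {
        sel <- pick(floor(b["ibd"] * m))
        H1[bb, sel] <- H1[a, sel]
        tibd <- b["ibd"] / 2; tibd2 <- 0
      } else {
        k2 <- floor(b["ibd2"] * m)
        k1 <- floor(2 * (b["ibd"] - b["ibd2"]) * m)
        sel <- pick(k2 + k1)
        sel2 <- sel[seq_len(k2)]
        sel1 <- sel[k2 + seq_len(k1)]
        H1[bb, sel2] <- H1[a, sel2]
        H2[bb, sel2] <- H2[a, sel2]
        H1[bb, sel1] <- H1[a, sel1]
        tibd <- b["ibd"]; tibd2 <- b["ibd2"]
      }
      pair_rows[[idx]] <- data.frame(id_a = ids[a], id_b = ids[bb],
                                     ibd = unname(tibd), ibd2 = unname(tibd2),
                                     stringsAsFactors = FALSE)
    }
  }
  true_ibd <- ibd_table(do.call(rbind, pair_rows))

  counts <- H1 + H2
  obs_cols <- seq_len(spec$m_observed)
  Gobs <- genotype_matrix(counts[, obs_cols, drop = FALSE],
                          sample_ids = ids,
                          snp_ids = sprintf("obs%05d", obs_cols),
                          haplotypes = if (keep_haplotypes)
                            list(H1[, obs_cols], H2[, obs_cols]) else NULL)
  Gun <- if (spec$m_unobserved > 0) {
    un_cols <- spec$m_observed + seq_len(spec$m_unobserved)
    genotype_matrix(counts[, un_cols, drop = FALSE], sample_ids = ids,
                    snp_ids = sprintf("unobs%05d", seq_len(spec$m_unobserved)),
                    haplotypes = if (keep_haplotypes)
                      list(H1[, un_cols], H2[, un_cols]) else NULL)
  } else NULL

  g_obs <- drop(.standardize_cols(Gobs$counts) %*%
                  rep(sqrt(spec$h2_observed / spec$m_observed),
                      spec$m_observed))
  g_un <- if (is.null(Gun)) 0 else
    drop(.standardize_cols(Gun$counts) %*%
           rep(sqrt(spec$h2_unobserved / spec$m_unobserved),
               spec$m_unobserved))
  noise_var <- 1 - spec$h2_observed - spec$h2_unobserved
  eps <- stats::rnorm(n, 0, sqrt(noise_var))
  # dominance-like component: every individual receives variance
  # shared_pair_var, correlated within a pair at its IBD2 fraction, i.e. a
  # draw from N(0, shared_pair_var * K_IBD2). Its covariance therefore loads
  # exactly on the IBD2 relationship matrix.
  shared <- numeric(n)
  if (spec$shared_pair_var > 0) {
    sdv <- sqrt(spec$shared_pair_var)
    shared <- sdv * stats::rnorm(n)
    for (k in seq_len(n_pairs)) {
      w <- true_ibd$pairs$ibd2[k]
      if (w > 0) {
        a <- 2L * k - 1L
        shared[2L * k] <- w * shared[a] +
          sqrt(1 - w^2) * shared[2L * k]
      }
    }
  }
  trait <- g_obs + g_un + shared + eps

  pheno <- data.frame(
    id = ids, trait = trait,
    age = round(stats::runif(n, 20, 80)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    region = sample(paste0("R", 1:3), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  structure(
    list(observed = Gobs, unobserved = Gun, true_ibd = true_ibd,
         phenotype = pheno,
         true_params = list(h2_total = spec$h2_observed + spec$h2_unobserved,
                            h2_g = spec$h2_observed),
         genetic_values = list(observed = g_obs,
                               unobserved = if (is.null(Gun)) NULL else g_un),
         maf = p, spec = spec),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", length(x$phenotype$id), "individuals,",
      x$spec$m_observed, "observed +", x$spec$m_unobserved,
      "unobserved SNPs\n")
  cat("  true h2_total =", x$true_params$h2_total,
      ", h2_g =", x$true_params$h2_g, "\n")
  invisible(x)
}

#' Split-chromosome phenotype simulation on real genotypes
#'
#' Mirrors the validation design used with real genotype panels: causal
#' variants are picked every `spacing`-th SNP (in map order) along the even
#' chromosomes (set C1, standing for the observed/genotyped panel) and along
#' the odd chromosomes (set C2, standing for variants not in LD with the
#' panel). Each sub-phenotype is the sum of raw allele counts (0/1/2) times
#' the set's effect size plus normal noise; the final phenotype is their
#' sum. True heritabilities are computed from the realized genotypic
#' variances, with h2_g the share contributed by the even chromosomes.
#'
#' @param G a [genotype_matrix()] whose `map` has a `chrom` column with at
#'   least one even and one odd chromosome.
#' @param spacing pick every `spacing`-th SNP (starting from the first) of
#'   each parity as causal.
#' @param alpha1,alpha2 effect sizes for C1 (even) and C2 (odd); scalars or
#'   per-causal-SNP vectors.
#' @param noise1,noise2 noise variances of the two sub-phenotypes.
#' @param seed integer seed.
#' @return A list with `phenotype` (data frame `id`, `trait`), `true_params`
#'   (`h2_total`, `h2_g`), and the causal index sets `C1`, `C2`.
#' @export
split_chromosome_phenotype <- function(G, spacing = 500, alpha1 = 0.1,
                                       alpha2 = 0.1, noise1 = 0.5,
                                       noise2 = 0.5, seed = 1L) {
  if (is.null(G$map) || is.null(G$map$chrom))
    stop("G$map must carry a 'chrom' column")
  if (spacing < 1) stop("spacing must be >= 1")
  chrom <- suppressWarnings(as.integer(G$map$chrom))
  if (anyNA(chrom)) stop("non-numeric chromosome labels")
  if (length(unique(chrom)) < 2) stop("need at least 2 chromosomes")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  pick_parity <- function(even) {
    snps <- which(if (even) chrom %% 2L == 0L else chrom %% 2L == 1L)
    if (length(snps) == 0) {
      warning("no SNPs on ", if (even) "even" else "odd",
              " chromosomes; empty causal set")
      return(integer(0))
    }
    sel <- snps[seq(1L, length(snps), by = spacing)]
    if (length(sel) == 0)
      warning("spacing exceeds the number of ",
              if (even) "even" else "odd", "-chromosome SNPs; empty causal set")
    sel
  }
  C1 <- pick_parity(TRUE)
  C2 <- pick_parity(FALSE)
  n <- nrow(G$counts)
  sub_pheno <- function(Cset, alpha, nv) {
    g <- if (length(Cset) == 0) numeric(n) else
      drop(G$counts[, Cset, drop = FALSE] %*% rep_len(alpha, length(Cset)))
    list(g = g, y = g + stats::rnorm(n, 0, sqrt(nv)))
  }
  s1 <- sub_pheno(C1, alpha1, noise1)
  s2 <- sub_pheno(C2, alpha2, noise2)
  vg1 <- stats::var(s1$g); vg2 <- stats::var(s2$g)
  vtot <- vg1 + vg2 + noise1 + noise2
  list(
    phenotype = data.frame(id = G$sample_ids, trait = s1$y + s2$y,
                           stringsAsFactors = FALSE),
    true_params = list(h2_total = (vg1 + vg2) / vtot, h2_g = vg1 / vtot),
    C1 = C1, C2 = C2
  )
}

#' Run replicated simulations through the heritability estimators
#'
#' Generates `n_replicates` cohorts from `spec` (replicate r uses seed
#' `spec$seed + r`), builds the relationship matrices each estimator needs,
#' fits, and collects per-replicate estimates with a mean/sd summary. This
#' is the parameter-recovery harness behind the validation experiments.
#'
#' @param spec a [simulation_spec()].
#' @param n_replicates number of replicates.
#' @param estimators subset of `"ibd"`, `"ibs"`, `"ibs_thr"`, `"joint_thr"`,
#'   `"joint_ibd"`.
#' @param t IBS threshold for the thresholded estimators.
#' @param constrain passed to the REML fits.
#' @param progress print a dot per replicate.
#' @return An object of class `replicate_study`: list with `replicates`
#'   (long data frame: replicate, estimator, h2_total, h2_g, ratio) and
#'   `summary` (per-estimator mean and empirical sd).
#' @export
replicate_study <- function(spec, n_replicates,
                            estimators = c("ibd", "ibs_thr", "joint_thr"),
                            t = 0.05, constrain = TRUE, progress = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"), n_replicates >= 1)
  known <- c("ibd", "ibs", "ibs_thr", "joint_thr", "joint_ibd")
  estimators <- match.arg(estimators, known, several.ok = TRUE)
  if (spec$seed + n_replicates >= 2^31 - 1) stop("seed too large")
  need_ibs <- any(estimators %in% c("ibs", "ibs_thr", "joint_thr", "joint_ibd"))
  rows <- vector("list", n_replicates * length(estimators))
  ri <- 0L
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + r
    sim <- simulate_cohort(spec_r)
    ids <- sim$phenotype$id
    K_ibd <- if (any(estimators %in% c("ibd", "joint_ibd")))
      build_ibd(sim$true_ibd, ids) else NULL
    K_ibs <- if (need_ibs) build_ibs(sim$observed) else NULL
    K_thr <- if (any(estimators %in% c("ibs_thr", "joint_thr")))
      threshold_ibs(K_ibs, t) else NULL
    for (est in estimators) {
      rep_out <- switch(
        est,
        ibd = estimate_h2(trait ~ 1, sim$phenotype, K_ibd,
                          constrain = constrain),
        ibs = estimate_h2(trait ~ 1, sim$phenotype, K_ibs,
                          constrain = constrain),
        ibs_thr = estimate_h2(trait ~ 1, sim$phenotype, K_thr,
                              constrain = constrain),
        joint_thr = estimate_joint(trait ~ 1, sim$phenotype, K_thr, K_ibs,
                                   constrain = constrain),
        joint_ibd = estimate_joint(trait ~ 1, sim$phenotype, K_ibd, K_ibs,
                                   constrain = constrain)
      )
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        replicate = r, estimator = est,
        h2_total = rep_out$h2_total, h2_g = rep_out$h2_g,
        ratio = rep_out$ratio_h2g_over_h2, stringsAsFactors = FALSE)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$estimator), function(d) {
    data.frame(estimator = d$estimator[1], n = nrow(d),
               mean_h2_total = mean(d$h2_total), sd_h2_total = stats::sd(d$h2_total),
               mean_h2_g = mean(d$h2_g), sd_h2_g = stats::sd(d$h2_g),
               mean_ratio = mean(d$ratio), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ, spec = spec, t = t),
            class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, digits = 4, ...) {
  cat("replicate_study:", max(x$replicates$replicate), "replicates\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) if (is.numeric(v)) round(v, digits) else v)
  print(s)
  invisible(x)
}
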