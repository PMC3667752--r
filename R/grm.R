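#' Build the standardized IBS relationship matrix from genotypes
#'
#' The off-diagonal entry for samples j and k is the allele-frequency-
#' standardized genotype correlation
#' \deqn{A_{jk} = \frac{1}{N}\sum_{i=1}^{N}
#'   \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)},}
#' where \eqn{x_{ij}} is the allele count (0, 1, 2) and \eqn{p_i} the
#' in-sample frequency of the counted allele of SNP i. The diagonal entry is
#' one plus an estimate of the inbreeding coefficient,
#' \deqn{A_{jj} = 1 + \frac{1}{N}\sum_{i=1}^{N}
#'   \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}.}
#' Missing genotypes are imputed to their per-SNP mean \eqn{2p_i} (a zero
#' standardized score), with frequencies estimated over non-missing samples.
#'
#' @param G a [genotype_matrix()]; all SNPs must be polymorphic in-sample
#'   (see [drop_monomorphic()]).
#' @return A [kinship_matrix()] of kind `"IBS"`.
#' @export
build_ibs <- function(G) {
  p <- G$freqs
  degen <- p <= 0 | p >= 1
  if (any(degen))
    stop("monomorphic SNP(s) with allele frequency 0 or 1: ",
         paste(utils::head(G$snp_ids[degen], 5), collapse = ", "),
         if (sum(degen) > 5) " ..." else "",
         " (drop_monomorphic() removes them)")
  X <- G$counts
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    for (i in which(colSums(is.na(X)) > 0))
      X[is.na(X[, i]), i] <- 2 * p[i]
  }
  N <- ncol(X)
  den <- 2 * p * (1 - p)
  Z <- sweep(X, 2, 2 * p, "-")
  Zs <- sweep(Z, 2, sqrt(den), "/")
  A <- tcrossprod(Zs) / N
  # diagonal: inbreeding estimator, not the sum of squared scores
  num_diag <- sweep(X * X - sweep(X, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  diag(A) <- 1 + rowSums(sweep(num_diag, 2, den, "/")) / N
  kinship_matrix(A, kind = "IBS", sample_ids = G$sample_ids)
}

#' Threshold an IBS relationship matrix
#'
#' Sets every off-diagonal entry at or below the threshold `t` to zero; the
#' diagonal is never changed. The result is tagged `"IBS_THRESHOLDED"` with
#' the threshold recorded. Zeroing distant relationships focuses the matrix
#' on close relatives, whose large entries estimate pairwise IBD well.
#'
#' Entries exactly equal to `t` are zeroed, so the documented `t = 0` setting
#' removes the numerically mean-zero (frequently negative or zero) distant
#' entries. The operation is idempotent.
#'
#' @param K a [kinship_matrix()] of kind `"IBS"` (or `"IBS_THRESHOLDED"`,
#'   for re-thresholding at a higher `t`).
#' @param t non-negative threshold; the conventional default is 0.05.
#' @return A [kinship_matrix()] of kind `"IBS_THRESHOLDED"`.
#' @export
threshold_ibs <- function(K, t = 0.05) {
  if (!inherits(K, "kinship_matrix")) stop("K must be a kinship_matrix")
  if (!K$kind %in% c("IBS", "IBS_THRESHOLDED"))
    stop("threshold_ibs() applies to IBS matrices, not kind ", K$kind)
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("threshold t must be a single non-negative number")
  V <- K$values
  d <- diag(V)
  V[V <= t] <- 0
  diag(V) <- d
  kinship_matrix(V, kind = "IBS_THRESHOLDED", sample_ids = K$sample_ids,
                 threshold = t, centered = K$centered)
}

#' Center the off-diagonal of an IBS relationship matrix
#'
#' Subtracts the grand mean of the off-diagonal entries from every
#' off-diagonal entry so that the expected relatedness of a random pair is
#' zero; the diagonal is untouched. IBS-type matrices are centered before
#' model fitting; IBD-type matrices are not, and passing one is an error.
#' Centering an already-centered matrix is a no-op (with a message).
#'
#' @param K a [kinship_matrix()] of kind `"IBS"` or `"IBS_THRESHOLDED"`.
#' @return The centered [kinship_matrix()] with `centered = TRUE`.
#' @export
center_ibs <- function(K) {
  if (!inherits(K, "kinship_matrix")) stop("K must be a kinship_matrix")
  if (!K$kind %in% c("IBS", "IBS_THRESHOLDED"))
    stop("IBD-type matrices are not centered (kind ", K$kind, ")")
  if (isTRUE(K$centered)) {
    message("kinship matrix already centered; returning unchanged")
    return(K)
  }
  V <- K$values
  off <- row(V) != col(V)
  V[off] <- V[off] - mean(V[off])
  kinship_matrix(V, kind = K$kind, sample_ids = K$sample_ids,
                 threshold = K$threshold, centered = TRUE)
}

#' Build an IBD relationship matrix from a pairwise IBD table
#'
#' The off-diagonal entry for a pair is the fraction of the genome shared
#' identical by descent (single-chromosome sharing weighted 1/2, both
#' chromosomes 1, so full siblings average 0.5). The diagonal entry is 1
#' plus the fraction of the genome shared IBD between the individual's
#' maternal and paternal copies (the table's self-record; 0 when absent).
#'
#' @param tab an [ibd_table()].
#' @param ids sample identifiers defining the matrix rows; pairs absent from
#'   the table get 0.
#' @return A [kinship_matrix()] of kind `"IBD"`.
#' @export
build_ibd <- function(tab, ids) {
  .build_ibd_kind(tab, ids, use_ibd2 = FALSE)
}

#' Build an IBD2 relationship matrix from a pairwise IBD table
#'
#' As [build_ibd()], but the off-diagonal entry is the fraction of the
#' genome with *both* chromosomes shared IBD (0.25 in expectation for full
#' siblings, 0 for parent-offspring pairs) and the diagonal is exactly 1.
#'
#' @inheritParams build_ibd
#' @return A [kinship_matrix()] of kind `"IBD2"`.
#' @export
build_ibd2 <- function(tab, ids) {
  .build_ibd_kind(tab, ids, use_ibd2 = TRUE)
}

#' Greedily prune related individuals from a kinship matrix
#'
#' Repeatedly removes the individual involved in the largest number of
#' off-diagonal entries above `threshold` until none remain, mimicking the
#' conventional relatedness filter applied before estimating SNP
#' heritability on "unrelated" samples. Deterministic: ties are broken by
#' sample order.
#'
#' @param K a [kinship_matrix()].
#' @param threshold relatedness cutoff; the conventional value is 0.025.
#' @return Character vector of sample identifiers to keep.
#' @export
prune_related <- function(K, threshold = 0.025) {
  V <- K$values
  diag(V) <- 0
  rel <- V > threshold
  storage.mode(rel) <- "integer"
  keep <- rep(TRUE, nrow(V))
  deg <- rowSums(rel)
  repeat {
    worst <- which.max(deg)
    if (deg[worst] == 0) break
    keep[worst] <- FALSE
    deg <- deg - rel[, worst] * keep   # drop its edges from remaining nodes
    deg[worst] <- 0L
  }
  K$sample_ids[keep]
}

.build_ibd_kind <- function(tab, ids, use_ibd2) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated sample ids")
  n <- length(ids)
  V <- diag(1, n)
  p <- tab$pairs
  if (nrow(p) > 0) {
    sel <- p$id_a %in% ids & p$id_b %in% ids & p$id_a != p$id_b
    if (any(sel)) {
      i <- match(p$id_a[sel], ids)
      j <- match(p$id_b[sel], ids)
      v <- if (use_ibd2) p$ibd2[sel] else p$ibd[sel]
      V[cbind(i, j)] <- v
      V[cbind(j, i)] <- v
    }
    if (!use_ibd2) {
      self <- p$id_a == p$id_b & p$id_a %in% ids
      if (any(self))
        V[cbind(match(p$id_a[self], ids), match(p$id_a[self], ids))] <-
          1 + p$ibd[self]
    }
  }
  kinship_matrix(V, kind = if (use_ibd2) "IBD2" else "IBD", sample_ids = ids)
}
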