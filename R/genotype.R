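#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs matrix of allele counts (0, 1, 2 or `NA`)
#' together with sample identifiers, SNP identifiers, in-sample allele
#' frequencies of the counted allele, an optional pair of haplotype matrices,
#' and an optional SNP map (chromosome and position).
#'
#' @param counts integer matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of row identifiers; defaults to
#'   `rownames(counts)` or `S1..Sn`.
#' @param snp_ids character vector of column identifiers; defaults to
#'   `colnames(counts)` or `snp1..snpm`.
#' @param freqs per-SNP allele frequency of the counted allele. When `NULL`
#'   (the default) frequencies are computed in-sample as the mean count over
#'   non-missing entries divided by 2.
#' @param haplotypes optional list of two binary matrices whose elementwise
#'   sum equals `counts` wherever `counts` is non-missing.
#' @param map optional data frame with one row per SNP; a `chrom` column is
#'   used by [split_chromosome_phenotype()].
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_plink()], [build_ibs()], [simulate_cohort()]
#' @export
genotype_matrix <- function(counts, sample_ids = NULL, snp_ids = NULL,
                            freqs = NULL, haplotypes = NULL, map = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(counts)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(counts)))
  }
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(counts))
    stop("length(sample_ids) must equal nrow(counts)")
  if (length(snp_ids) != ncol(counts))
    stop("length(snp_ids) must equal ncol(counts)")
  bad <- !(counts %in% c(0L, 1L, 2L)) & !is.na(counts)
  if (any(bad))
    stop("genotype counts must be 0, 1, 2 or NA; found ",
         paste(unique(counts[bad])[seq_len(min(3, sum(bad)))], collapse = ", "))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, snp_ids)
  if (is.null(freqs)) {
    freqs <- colMeans(counts, na.rm = TRUE) / 2
  } else {
    if (length(freqs) != ncol(counts))
      stop("length(freqs) must equal the number of SNPs")
  }
  freqs <- as.numeric(freqs)
  if (!is.null(haplotypes)) {
    stopifnot(is.list(haplotypes), length(haplotypes) == 2)
    h1 <- haplotypes[[1]]; h2 <- haplotypes[[2]]
    if (!all(dim(h1) == dim(counts)) || !all(dim(h2) == dim(counts)))
      stop("haplotype matrices must have the same dimensions as counts")
    s <- h1 + h2
    ok <- is.na(counts) | s == counts
    if (!all(ok))
      stop("haplotypes must sum to counts at all non-missing entries")
  }
  if (!is.null(map) && nrow(map) != ncol(counts))
    stop("map must have one row per SNP")
  structure(
    list(counts = counts, sample_ids = sample_ids, snp_ids = snp_ids,
         freqs = freqs, haplotypes = haplotypes, map = map),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  nm <- sum(is.na(x$counts))
  if (nm > 0) cat("  missing entries:", nm, "\n")
  cat("  allele frequency range:",
      sprintf("%.3f - %.3f", min(x$freqs), max(x$freqs)), "\n")
  if (!is.null(x$haplotypes)) cat("  haplotypes: present\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Drop monomorphic SNPs
#'
#' Removes SNPs whose in-sample allele frequency is 0 or 1 (no variation),
#' which would make the standardized-genotype kinship of [build_ibs()]
#' undefined.
#'
#' @param G a [genotype_matrix()].
#' @return A `genotype_matrix` restricted to polymorphic SNPs.
#' @export
drop_monomorphic <- function(G) {
  keep <- G$freqs > 0 & G$freqs < 1
  if (all(keep)) return(G)
  genotype_matrix(G$counts[, keep, drop = FALSE],
                  sample_ids = G$sample_ids,
                  snp_ids = G$snp_ids[keep],
                  freqs = G$freqs[keep],
                  map = if (is.null(G$map)) NULL else G$map[keep, , drop = FALSE])
}

#' Subset a genotype matrix by sample identifier
#'
#' Allele frequencies are recomputed in-sample after subsetting.
#'
#' @param G a [genotype_matrix()].
#' @param ids sample identifiers to keep, in the order requested.
#' @return A `genotype_matrix` for the requested samples.
#' @export
subset_samples <- function(G, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, G$sample_ids)
  if (length(miss) > 0)
    stop("unknown sample ids: ", paste(utils::head(miss, 3), collapse = ", "))
  idx <- match(ids, G$sample_ids)
  genotype_matrix(G$counts[idx, , drop = FALSE], sample_ids = ids,
                  snp_ids = G$snp_ids, map = G$map)
}
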