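#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Decodes the SNP-major PLINK 1 binary genotype format. Counts refer to the
#' A1 allele of the .bim file: the 2-bit codes map as homozygous-A2 -> 0,
#' heterozygote -> 1, homozygous-A1 -> 2, and the missing code is preserved
#' as `NA`.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return A [genotype_matrix()] with the .bim table attached as `map`.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)

  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  colnames(bim_df) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")[seq_len(ncol(bim_df))]
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  sample_ids <- as.character(fam_df[[2]])
  snp_ids <- as.character(bim_df$snp_id)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic bytes in ", bed)
  if (raw[3] == as.raw(0x00))
    stop("individual-major .bed layout is not supported")
  if (raw[3] != as.raw(0x01))
    stop("unknown .bed mode byte: ", as.integer(raw[3]))

  bps <- ceiling(n / 4)  # bytes per SNP block
  if (length(raw) - 3L != bps * m)
    stop(".bed payload is ", length(raw) - 3L, " bytes; expected ", bps * m,
         " for ", n, " samples x ", m, " SNPs")

  bytes <- as.integer(raw[-(1:3)])
  dim(bytes) <- c(bps, m)
  # expand each byte into 4 two-bit codes, low bits = first sample
  codes <- matrix(0L, 4L * bps, m)
  codes[seq(1L, 4L * bps, by = 4L), ] <- bytes %% 4L
  codes[seq(2L, 4L * bps, by = 4L), ] <- (bytes %/% 4L) %% 4L
  codes[seq(3L, 4L * bps, by = 4L), ] <- (bytes %/% 16L) %% 4L
  codes[seq(4L, 4L * bps, by = 4L), ] <- bytes %/% 64L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 01 -> missing, 10 -> het, 11 -> 0 copies
  decode <- c(2L, NA_integer_, 1L, 0L)
  counts <- matrix(decode[codes + 1L], nrow = n, ncol = m)

  genotype_matrix(counts, sample_ids = sample_ids, snp_ids = snp_ids,
                  map = bim_df)
}

#' Write a PLINK .bed/.bim/.fam fileset
#'
#' @param G a [genotype_matrix()]. If `G$map` has `chrom`/`pos`/`a1`/`a2`
#'   columns they are written to the .bim file; otherwise placeholders are
#'   used (chromosome 1, position = SNP index, alleles A/B).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  counts <- G$counts
  n <- nrow(counts); m <- ncol(counts)
  map <- G$map
  bim_df <- data.frame(
    chrom = if (!is.null(map$chrom)) map$chrom else rep(1L, m),
    snp_id = G$snp_ids,
    cm = 0,
    pos = if (!is.null(map$pos)) map$pos else seq_len(m),
    a1 = if (!is.null(map$a1)) map$a1 else rep("A", m),
    a2 = if (!is.null(map$a2)) map$a2 else rep("B", m),
    stringsAsFactors = FALSE
  )
  fam_df <- data.frame(fid = G$sample_ids, iid = G$sample_ids,
                       pat = 0L, mat = 0L, sex = 0L, pheno = -9L,
                       stringsAsFactors = FALSE)
  utils::write.table(bim_df, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(fam_df, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)

  # counts -> 2-bit codes: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  encode <- c(3L, 2L, 0L)
  codes <- matrix(1L, nrow = n, ncol = m)  # missing code
  ok <- !is.na(counts)
  codes[ok] <- encode[counts[ok] + 1L]
  bps <- ceiling(n / 4)
  pad <- 4L * bps - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = m))
  dim(codes) <- c(4L, bps * m)
  bytes <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a plain-text genotype matrix
#'
#' Whitespace-delimited text with a header row; the first column holds sample
#' identifiers and the remaining columns per-SNP allele counts (0/1/2, `NA`
#' for missing).
#'
#' @param path input file.
#' @return A [genotype_matrix()].
#' @export
read_geno_text <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(counts, sample_ids = as.character(df[[1]]),
                  snp_ids = colnames(df)[-1])
}

#' Write a genotype matrix as plain text
#'
#' Tab-delimited UTF-8 with a header row (`id` followed by SNP identifiers).
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geno_text <- function(G, path) {
  df <- data.frame(id = G$sample_ids, G$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", G$snp_ids)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
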