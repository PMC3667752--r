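#' Read a GCTA binary GRM
#'
#' Reads the GCTA relationship-matrix triple: `prefix.grm.bin` (lower
#' triangle including the diagonal, row by row, 4-byte little-endian reals),
#' `prefix.grm.id` (two-column text, family and individual id) and, when
#' present, `prefix.grm.N.bin` (per-pair SNP counts, same layout).
#'
#' @param prefix path prefix of the GRM triple.
#' @param kind the [kinship_matrix()] kind to tag the result with; GCTA GRMs
#'   are IBS-type by construction, so the default is `"IBS"`.
#' @return A [kinship_matrix()]; when `prefix.grm.N.bin` exists the per-pair
#'   counts are attached as attribute `"n_snps"`.
#' @export
read_grm_gcta <- function(prefix, kind = "IBS") {
  bin <- paste0(prefix, ".grm.bin")
  idf <- paste0(prefix, ".grm.id")
  for (f in c(bin, idf)) if (!file.exists(f)) stop("file not found: ", f)
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  sz <- file.size(bin)
  if (sz != 4 * ntri)
    stop("truncated GRM: ", bin, " has ", sz, " bytes; expected ", 4 * ntri,
         " for ", n, " ids")
  tri <- readBin(bin, what = "numeric", n = ntri, size = 4, endian = "little")
  V <- matrix(0, n, n)
  V[upper.tri(V, diag = TRUE)] <- tri  # column-major upper == row-major lower
  V <- V + t(V) - diag(diag(V))
  K <- kinship_matrix(V, kind = kind, sample_ids = as.character(ids[[2]]))
  nbin <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nbin) && file.size(nbin) == 4 * ntri) {
    ntri_v <- readBin(nbin, what = "numeric", n = ntri, size = 4,
                      endian = "little")
    N <- matrix(0, n, n)
    N[upper.tri(N, diag = TRUE)] <- ntri_v
    N <- N + t(N) - diag(diag(N))
    attr(K, "n_snps") <- N
  }
  K
}

#' Write a GCTA binary GRM
#'
#' Writes `prefix.grm.bin`, `prefix.grm.id` and `prefix.grm.N.bin` in the
#' 4-byte-real GCTA dialect. Note that 4-byte storage rounds values to
#' single precision.
#'
#' @param K a [kinship_matrix()].
#' @param prefix output path prefix.
#' @param n_snps per-pair SNP count for `prefix.grm.N.bin`: a scalar or a
#'   symmetric matrix. Defaults to the `"n_snps"` attribute of `K` if set,
#'   else 0.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(K, prefix, n_snps = NULL) {
  V <- K$values
  n <- nrow(V)
  tri <- V[upper.tri(V, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4, endian = "little")
  close(con)
  if (is.null(n_snps)) n_snps <- attr(K, "n_snps")
  if (is.null(n_snps)) n_snps <- 0
  Nm <- if (length(n_snps) == 1) matrix(n_snps, n, n) else as.matrix(n_snps)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(Nm[upper.tri(Nm, diag = TRUE)]), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(
    data.frame(fid = K$sample_ids, iid = K$sample_ids),
    paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
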