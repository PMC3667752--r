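#' Kinship (genetic relationship) matrix container
#'
#' A symmetric n-by-n relatedness matrix tagged with its kind, used as the
#' covariance structure of a random genetic effect in [greml()]. Four kinds
#' are supported, matching the estimators of the toolbox:
#'
#' * `"IBS"` — standardized identity-by-state correlation computed from
#'   genotypes ([build_ibs()]); diagonal is 1 + an inbreeding estimate.
#' * `"IBS_THRESHOLDED"` — the IBS matrix with all off-diagonal entries at or
#'   below a threshold `t` set to 0 ([threshold_ibs()]); the diagonal is
#'   never changed.
#' * `"IBD"` — pairwise fraction of the genome shared identical by descent;
#'   diagonal is 1 plus the maternal-paternal sharing fraction
#'   ([build_ibd()]).
#' * `"IBD2"` — pairwise fraction of the genome with both chromosomes shared
#'   IBD; diagonal is exactly 1 ([build_ibd2()]).
#'
#' @param values symmetric numeric matrix (tolerance 1e-12; tiny asymmetries
#'   are symmetrized).
#' @param kind one of `"IBS"`, `"IBS_THRESHOLDED"`, `"IBD"`, `"IBD2"`.
#' @param sample_ids character identifiers for rows/columns.
#' @param threshold the threshold used, for kind `"IBS_THRESHOLDED"`.
#' @param centered logical; whether the off-diagonal grand mean has been
#'   subtracted ([center_ibs()]).
#'
#' @return An object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(values, kind = c("IBS", "IBS_THRESHOLDED", "IBD", "IBD2"),
                           sample_ids = NULL, threshold = NULL, centered = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kinship matrix must be square")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-12)
    stop("kinship matrix is not symmetric (max asymmetry ", signif(asym, 3), ")")
  values <- (values + t(values)) / 2
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(
    list(values = values, kind = kind, sample_ids = sample_ids,
         threshold = threshold, centered = centered),
    class = "kinship_matrix"
  )
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) x$values

#' @export
dim.kinship_matrix <- function(x) dim(x$values)

#' @export
print.kinship_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat("kinship_matrix (", x$kind, "): ", n, " x ", n, "\n", sep = "")
  off <- x$values[upper.tri(x$values)]
  if (length(off) > 0)
    cat(sprintf("  off-diagonal: mean %.4g, range [%.4g, %.4g]\n",
                mean(off), min(off), max(off)))
  cat(sprintf("  diagonal: mean %.4g\n", mean(diag(x$values))))
  if (!is.null(x$threshold)) cat("  threshold:", x$threshold, "\n")
  if (isTRUE(x$centered)) cat("  centered: yes\n")
  invisible(x)
}

#' Subset a kinship matrix by sample identifier
#'
#' @param K a [kinship_matrix()].
#' @param ids identifiers to keep, in the order requested.
#' @return A `kinship_matrix` for the requested samples.
#' @export
subset_kinship <- function(K, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, K$sample_ids)
  if (length(miss) > 0)
    stop("unknown sample ids in kinship matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  idx <- match(ids, K$sample_ids)
  kinship_matrix(K$values[idx, idx, drop = FALSE], kind = K$kind,
                 sample_ids = ids, threshold = K$threshold,
                 centered = K$centered)
}

# Deterministic sample alignment: identifiers common to all inputs, kept in
# the order they appear in the first.
align_ids <- function(...) {
  lists <- list(...)
  ids <- lists[[1]]
  for (l in lists[-1]) ids <- ids[ids %in% l]
  if (length(ids) == 0) stop("no samples in common between inputs")
  ids
}
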