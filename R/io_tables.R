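#' Pairwise IBD table
#'
#' A symmetric table of pairwise genome-sharing fractions: for each pair the
#' fraction of the genome shared identical by descent (`ibd`, weighting
#' single-chromosome sharing by 1/2 and double by 1) and the fraction with
#' both chromosomes shared (`ibd2`). Rows with `id_a == id_b` are
#' self-records whose `ibd` value is the maternal-paternal sharing fraction
#' used on the diagonal of [build_ibd()]. Absent pairs imply 0.
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `ibd`, `ibd2`
#'   (missing `ibd2` column defaults to 0).
#' @return An object of class `ibd_table`.
#' @seealso [read_ibd_table()], [ibd_lookup()], [build_ibd()], [build_ibd2()]
#' @export
ibd_table <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(id_a = character(), id_b = character(),
                        ibd = numeric(), ibd2 = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) < 3) stop("ibd table needs columns id_a, id_b, ibd[, ibd2]")
    if (ncol(pairs) == 3) pairs$ibd2 <- 0
    pairs <- pairs[, 1:4]
    colnames(pairs) <- c("id_a", "id_b", "ibd", "ibd2")
    pairs$id_a <- as.character(pairs$id_a)
    pairs$id_b <- as.character(pairs$id_b)
    if (any(!is.finite(pairs$ibd)) || any(!is.finite(pairs$ibd2)))
      stop("non-finite ibd values")
    if (any(pairs$ibd < 0 | pairs$ibd > 1 | pairs$ibd2 < 0 | pairs$ibd2 > 1))
      stop("ibd and ibd2 fractions must lie in [0, 1]")
    bad <- pairs$ibd2 > pairs$ibd + 1e-12
    if (any(bad))
      stop("ibd2 exceeds ibd for pair(s): ",
           paste(utils::head(paste(pairs$id_a[bad], pairs$id_b[bad]), 3),
                 collapse = "; "))
    # conflicting duplicate/asymmetric records are an error
    key <- ifelse(pairs$id_a <= pairs$id_b,
                  paste(pairs$id_a, pairs$id_b, sep = "\r"),
                  paste(pairs$id_b, pairs$id_a, sep = "\r"))
    if (anyDuplicated(key)) {
      agg <- tapply(seq_len(nrow(pairs)), key, function(i) {
        length(unique(pairs$ibd[i])) > 1 || length(unique(pairs$ibd2[i])) > 1
      })
      if (any(agg)) stop("conflicting records for pair(s): ",
                         paste(utils::head(gsub("\r", "/", names(agg)[agg]), 3),
                               collapse = "; "))
      pairs <- pairs[!duplicated(key), , drop = FALSE]
      key <- key[!duplicated(key)]
    }
    rownames(pairs) <- NULL
    attr(pairs, "key") <- key
  }
  structure(list(pairs = pairs), class = "ibd_table")
}

#' @export
print.ibd_table <- function(x, ...) {
  p <- x$pairs
  self <- p$id_a == p$id_b
  cat("ibd_table:", sum(!self), "pair records,", sum(self), "self records\n")
  invisible(x)
}

#' Look up pairwise IBD fractions
#'
#' Symmetric lookup: `(a, b)` and `(b, a)` return the same record; absent
#' pairs return 0 for both fractions, and absent self-records return a
#' selfing fraction of 0.
#'
#' @param tab an [ibd_table()].
#' @param a,b sample identifiers (vectors of equal length are recycled
#'   elementwise).
#' @return A data frame with columns `ibd` and `ibd2`.
#' @export
ibd_lookup <- function(tab, a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  p <- tab$pairs
  if (nrow(p) == 0) return(data.frame(ibd = numeric(n), ibd2 = numeric(n)))
  key <- ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  idx <- match(key, attr(p, "key"))
  out <- data.frame(ibd = ifelse(is.na(idx), 0, p$ibd[idx]),
                    ibd2 = ifelse(is.na(idx), 0, p$ibd2[idx]))
  out
}

#' Read a pairwise IBD table from text
#'
#' Whitespace- or comma-delimited text with a header; the first two columns
#' are identifiers, the third the IBD fraction and the (optional) fourth the
#' IBD2 fraction. Rows with equal identifiers are self-records (maternal-
#' paternal sharing). An empty file yields an empty table where every lookup
#' returns 0.
#'
#' @param path input file.
#' @return An [ibd_table()].
#' @export
read_ibd_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(ibd_table())
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(ibd_table())
  ibd_table(df)
}

#' Write a pairwise IBD table as tab-delimited text
#'
#' @param tab an [ibd_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ibd_table <- function(tab, path) {
  utils::write.table(tab$pairs, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Whitespace- or comma-delimited text with a header row. One column (default
#' `id`) holds sample identifiers; the remainder are traits and covariates
#' (the conventional covariates being `age`, `sex`, `region`). Dichotomous
#' traits must contain only 0, 1 and missing values.
#'
#' @param path input file.
#' @param id_col name of the identifier column.
#' @return A data frame with character `id` first; character covariates are
#'   left as-is (model formulas coerce them to factors).
#' @export
read_pheno_table <- function(path, id_col = "id") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!id_col %in% colnames(df))
    stop("no '", id_col, "' column in ", path)
  df[[id_col]] <- as.character(df[[id_col]])
  df <- df[, c(id_col, setdiff(colnames(df), id_col)), drop = FALSE]
  colnames(df)[1] <- "id"
  if (anyDuplicated(df$id)) stop("duplicated sample ids in ", path)
  df
}

#' Write a phenotype/covariate table
#'
#' Tab-delimited UTF-8 with a header row.
#'
#' @param df data frame with an `id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
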