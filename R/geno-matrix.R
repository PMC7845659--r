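#' Genotype matrix container
#'
#' A light container for a subjects-by-variants matrix of allele counts.
#' Calls count copies of the alternate allele, so each entry is 0, 1, 2 or
#' `NA` (missing). Variant metadata travels alongside the calls and stays
#' aligned with the matrix columns.
#'
#' @param calls Integer matrix, subjects in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names, if absent, are taken from
#'   `subjects`.
#' @param variants A data frame with one row per variant and columns
#'   `id`, `chrom`, `pos`, `ref`, `alt` and optionally `is_chip`.
#' @param subjects Character vector of subject ids (defaults to the row
#'   names of `calls`, or `S1..Sn`).
#'
#' @return An object of class `geno_matrix`: the call matrix with a
#'   `variants` tibble attribute.
#' @export
geno_matrix <- function(calls, variants, subjects = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  variants <- tibble::as_tibble(variants)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"is_chip" %in% names(variants)) variants$is_chip <- FALSE
  if (nrow(variants) != ncol(calls)) {
    stop("variants table (", nrow(variants), " rows) does not match call matrix (",
         ncol(calls), " columns)", call. = FALSE)
  }
  if (anyDuplicated(variants$id)) stop("variant ids must be unique", call. = FALSE)
  if (any(variants$pos < 1)) stop("variant positions are 1-based and must be >= 1", call. = FALSE)
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ", call. = FALSE)
  if (is.null(subjects)) {
    subjects <- rownames(calls)
    if (is.null(subjects)) subjects <- sprintf("S%d", seq_len(nrow(calls)))
  }
  if (length(subjects) != nrow(calls)) stop("subject ids do not match call matrix rows", call. = FALSE)
  rownames(calls) <- subjects
  colnames(calls) <- variants$id
  structure(calls, variants = variants, class = c("geno_matrix", "matrix", "array"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x), " subjects x ", ncol(x), " variants; ",
      sum(is.na(x)), " missing calls\n", sep = "")
  invisible(x)
}

#' Variant metadata of a genotype matrix
#' @param x A `geno_matrix`.
#' @return A tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`, `is_chip`.
#' @export
variant_info <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  attr(x, "variants")
}

#' Subject ids of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(x) rownames(x)

#' Subset a genotype matrix
#'
#' Keeps the variant metadata aligned when selecting subjects and/or
#' variants.
#'
#' @param x A `geno_matrix`.
#' @param subjects,variants Index vectors (integer, logical or names) into
#'   rows and columns; `NULL` keeps everything.
#' @return A `geno_matrix`.
#' @export
geno_subset <- function(x, subjects = NULL, variants = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  vi <- variant_info(x)
  si <- if (is.null(subjects)) seq_len(nrow(x)) else subjects
  if (is.character(si)) si <- match(si, rownames(x))
  ji <- if (is.null(variants)) seq_len(ncol(x)) else variants
  if (is.character(ji)) ji <- match(ji, vi$id)
  if (is.logical(ji)) ji <- which(ji)
  calls <- unclass(x)[si, ji, drop = FALSE]
  attr(calls, "variants") <- NULL
  geno_matrix(calls, vi[ji, , drop = FALSE], subjects = rownames(x)[si])
}
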