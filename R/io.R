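#' Write genotypes as PLINK 1.9 bed/bim/fam
#'
#' Variant-major (SNP-major) binary layout with magic bytes
#' `0x6C 0x1B 0x01`. The alternate allele is written as A1 and the
#' reference as A2, so the on-disk codes are: 00 = 2 alt copies, 10 = het,
#' 11 = 0 alt copies, 01 = missing. Sex is coded 1 = male, 2 = female,
#' 0 = unknown in the fam file.
#'
#' @param genotypes A [geno_matrix()].
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @param subjects Optional tibble with `subject_id` and `sex` used to fill
#'   the fam sex column.
#' @param meta Optional list (e.g. seed and config hash); when supplied a
#'   `<prefix>.json` sidecar records it.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, subjects = NULL, meta = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  vi <- variant_info(genotypes)
  n <- nrow(genotypes); m <- ncol(genotypes)

  bim <- data.frame(vi$chrom, vi$id, 0L, vi$pos, vi$alt, vi$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  sex_code <- rep(0L, n)
  if (!is.null(subjects)) {
    sx <- subjects$sex[match(rownames(genotypes), subjects$subject_id)]
    sex_code <- ifelse(is.na(sx), 0L, ifelse(sx == "male", 1L, 2L))
  }
  fam <- data.frame(rownames(genotypes), rownames(genotypes), 0L, 0L, sex_code, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # 2-bit codes per sample: alt count 2 -> 0 (hom A1), 1 -> 2 (het),
  # 0 -> 3 (hom A2), NA -> 1 (missing)
  code <- matrix(3L, n, m)
  calls <- unclass(genotypes)
  code[calls == 2L] <- 0L
  code[calls == 1L] <- 2L
  code[is.na(calls)] <- 1L
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4 - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, nbytes, m)
  for (k in 1:4) {
    bytes <- bytes + code[seq(k, nbytes * 4, by = 4), , drop = FALSE] * shift[k]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  }
  invisible(prefix)
}

#' Read PLINK 1.9 bed/bim/fam genotypes
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A [geno_matrix()] with calls counting A1 (alternate) copies.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"),
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop("not a PLINK bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major PLINK bed files are supported", call. = FALSE)
  }
  nbytes <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != nbytes * m) {
    stop("bed payload size does not match bim/fam dimensions", call. = FALSE)
  }
  ints <- as.integer(payload)
  code <- matrix(NA_integer_, nbytes * 4, m)
  for (k in 1:4) {
    code[seq(k, nbytes * 4, by = 4), ] <- ints %% 4L
    ints <- ints %/% 4L
  }
  code <- code[seq_len(n), , drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  calls[code == 0L] <- 2L
  calls[code == 2L] <- 1L
  calls[code == 3L] <- 0L
  variants <- tibble::tibble(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                             ref = bim$a2, alt = bim$a1, is_chip = FALSE)
  geno_matrix(calls, variants, subjects = fam$iid)
}

#' Write / read an HRSD panel as TSV
#'
#' One row per subject-visit with columns `subject_id`, `cohort`, `sex`,
#' `age`, `week`, `item01`..`item21`; missing visits keep their row with
#' `NA` item scores.
#'
#' @param panel HRSD panel tibble.
#' @param subjects Subject covariate tibble (subject_id, cohort, sex, age).
#' @param path Output TSV path.
#' @param meta Optional list written to a `<path>.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_hrsd <- function(panel, subjects, path, meta = NULL) {
  out <- panel %>%
    dplyr::left_join(subjects %>% dplyr::select("subject_id", "cohort", "sex", "age"),
                     by = "subject_id") %>%
    dplyr::select("subject_id", "cohort", "sex", "age", "week",
                  dplyr::starts_with("item"))
  readr::write_tsv(out, path, na = "NA")
  if (!is.null(meta)) jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hrsd
#' @return `read_hrsd()`: a list with `panel` and `subjects` tibbles.
#' @export
read_hrsd <- function(path) {
  item_cols <- sprintf("item%02d", 1:21)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = "c", cohort = "c", sex = "c",
                           age = "d", week = "i", .default = "i"))
  known <- c("subject_id", "cohort", "sex", "age", "week", item_cols)
  extra <- setdiff(names(tab), known)
  if (length(extra)) stop("unknown column(s) in HRSD file: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  if (!nrow(tab)) {
    return(list(panel = tibble::tibble(subject_id = character(), week = integer()),
                subjects = tibble::tibble(subject_id = character(), cohort = character(),
                                          sex = character(), age = numeric())))
  }
  subjects <- tab %>% dplyr::distinct(.data$subject_id, .data$cohort, .data$sex, .data$age)
  panel <- tab %>% dplyr::select("subject_id", "week", dplyr::all_of(item_cols))
  list(panel = panel, subjects = subjects)
}

#' Write / read a derived phenotype table as TSV
#'
#' Round-trips the output of [build_phenotypes()]; `NA` encodes missing.
#'
#' @param table Phenotype tibble.
#' @param path TSV path.
#' @param meta Optional list written to a `<path>.json` sidecar.
#' @return `path` invisibly / the phenotype tibble.
#' @export
write_phenotypes <- function(table, path, meta = NULL) {
  readr::write_tsv(table, path, na = "NA")
  if (!is.null(meta)) jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(subject_id = "c", cohort = "c",
                                          sex = "c", drug = "c",
                                          response_code = "c", .default = "d"))
}

#' Read / write gene region tables
#'
#' Regions use 1-based, both-ends-inclusive coordinates (`gene_id`,
#' `chrom`, `start`, `end`) — note this differs from 0-based half-open
#' BED; use [bed_to_regions()] to convert.
#'
#' @param path TSV path with columns gene_id, chrom, start, end.
#' @return A tibble of gene regions.
#' @export
read_regions <- function(path) {
  reg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(gene_id = "c", chrom = "c",
                                                 start = "i", end = "i"))
  if (any(reg$start > reg$end)) stop("region start exceeds end", call. = FALSE)
  reg
}

#' @rdname read_regions
#' @param bed A tibble/data frame in BED convention (chrom, start, end,
#'   name), 0-based half-open.
#' @export
bed_to_regions <- function(bed) {
  tibble::tibble(gene_id = bed[[4]], chrom = as.character(bed[[1]]),
                 start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]))
}
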