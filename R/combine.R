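#' Inverse-gamma combination of p-values
#'
#' Each p-value is transformed to the upper-tail Gamma(alpha, 1) quantile;
#' the sum of the k transforms is referred to the upper tail of
#' Gamma(k * alpha, 1). With `alpha = 1` this is exactly Fisher's method
#' (`-2 ln p` terms against chi-square with 2k df), and a single p-value
#' is returned unchanged.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha Shape parameter (default 1 = Fisher).
#' @return Combined p-value in (0, 1].
#' @export
inverse_gamma_combine <- function(p_values, alpha = 1) {
  if (!length(p_values)) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  t_sum <- sum(stats::qgamma(p_values, shape = alpha, lower.tail = FALSE))
  stats::pgamma(t_sum, shape = length(p_values) * alpha, lower.tail = FALSE)
}

#' Merge two cohorts' genotypes into one pooled panel
#'
#' Intersects variants by id and aligns alleles: variants whose ref/alt
#' are swapped in the second panel have their dosages flipped (0 <-> 2);
#' strand-ambiguous variants (A/T or C/G) with MAF > `ambiguous_maf` and
#' variants with irreconcilable allele pairs are dropped and logged.
#'
#' @param genotypes_a,genotypes_b [geno_matrix()] objects.
#' @param ambiguous_maf MAF above which strand-ambiguous variants are
#'   dropped (default 0.4).
#' @return List with `genotypes` (pooled [geno_matrix()], subjects of A
#'   then B) and `log` (tibble id, action in flipped/dropped, reason).
#' @export
merge_cohorts <- function(genotypes_a, genotypes_b, ambiguous_maf = 0.4) {
  via <- variant_info(genotypes_a); vib <- variant_info(genotypes_b)
  common <- intersect(via$id, vib$id)
  log <- tibble::tibble(id = character(), action = character(), reason = character())
  if (!length(common)) {
    warning("no overlapping variant ids between cohorts")
    empty <- geno_matrix(matrix(integer(), 0, 0),
                         tibble::tibble(id = character(), chrom = character(),
                                        pos = integer(), ref = character(),
                                        alt = character()))
    return(list(genotypes = empty, log = log))
  }
  ia <- match(common, via$id); ib <- match(common, vib$id)
  same <- via$ref[ia] == vib$ref[ib] & via$alt[ia] == vib$alt[ib]
  swapped <- via$ref[ia] == vib$alt[ib] & via$alt[ia] == vib$ref[ib]
  ambiguous <- paste0(pmin(via$ref[ia], via$alt[ia]), pmax(via$ref[ia], via$alt[ia])) %in% c("AT", "CG")
  maf_a <- variant_stats(genotypes_a)$maf[ia]
  drop_amb <- ambiguous & !is.na(maf_a) & maf_a > ambiguous_maf
  drop_bad <- !(same | swapped)
  keep <- !(drop_amb | drop_bad)
  log <- dplyr::bind_rows(
    tibble::tibble(id = common[drop_bad], action = "dropped", reason = "allele_mismatch"),
    tibble::tibble(id = common[drop_amb & !drop_bad], action = "dropped",
                   reason = "strand_ambiguous"),
    tibble::tibble(id = common[swapped & keep], action = "flipped",
                   reason = "ref_alt_swapped")
  )
  common <- common[keep]; ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]
  calls_a <- unclass(genotypes_a)[, ia, drop = FALSE]
  calls_b <- unclass(genotypes_b)[, ib, drop = FALSE]
  calls_b[, swapped] <- 2L - calls_b[, swapped]
  pooled <- rbind(calls_a, calls_b)
  list(genotypes = geno_matrix(pooled, via[ia, , drop = FALSE],
                               subjects = c(rownames(genotypes_a), rownames(genotypes_b))),
       log = log)
}

#' Mega-analysis scan of pooled cohorts
#'
#' The same machinery as [scan_markers()] applied to the pooled panel from
#' [merge_cohorts()]; covariates default to age + sex (a cohort indicator
#' can be added via `covariates`).
#'
#' @param merged Result of [merge_cohorts()] (or a pooled [geno_matrix()]).
#' @param data Pooled phenotype tibble.
#' @inheritParams scan_markers
#' @return Tibble as [scan_markers()].
#' @export
mega_scan <- function(merged, data, outcome, covariates = c("age", "sex"),
                      family = c("linear", "logistic")) {
  geno <- if (inherits(merged, "geno_matrix")) merged else merged$genotypes
  scan_markers(geno, data, outcome, covariates = covariates, family = family)
}

#' Effective number of independent tests (Li & Ji)
#'
#' From the eigenvalues of the absolute dosage correlation matrix:
#' `Meff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`. Divides the
#' Bonferroni alpha for an LD-adjusted threshold.
#'
#' @param corr Square correlation matrix of M variants.
#' @return Meff, with `Meff <= M` and equality iff `corr` is the identity.
#' @export
meff_li_ji <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  lambda <- eigen(abs(corr), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Significance threshold scheme
#'
#' Marker tiers: significant 5e-4, suggestive 5e-3, weak 1e-2. Gene tiers:
#' significant 1e-2, suggestive 5e-2. Comparison is strict `<`.
#'
#' @param snp,gene Named numeric tier thresholds, ordered significant <
#'   suggestive (< weak).
#' @return List of class `threshold_scheme`.
#' @export
threshold_scheme <- function(snp = c(significant = 5e-4, suggestive = 5e-3, weak = 1e-2),
                             gene = c(significant = 1e-2, suggestive = 5e-2)) {
  if (is.unsorted(snp) || is.unsorted(gene)) {
    stop("tier thresholds must increase from significant to weak", call. = FALSE)
  }
  structure(list(snp = snp, gene = gene), class = "threshold_scheme")
}

tier_of <- function(p, tiers) {
  out <- rep("none", length(p))
  for (nm in rev(names(tiers))) out[!is.na(p) & p < tiers[[nm]]] <- nm
  out[is.na(p)] <- NA_character_
  out
}

#' Classify combined results into significance tiers
#'
#' Assigns a tier (strict `<` comparison) to the meta- and mega-analysis
#' p-value of each unit.
#'
#' @param results Tibble with columns `meta_p` and `mega_p`.
#' @param scheme A [threshold_scheme()].
#' @param unit `"snp"` or `"gene"` (selects the tier table).
#' @return `results` with added `meta_tier` and `mega_tier` columns.
#' @export
classify_hits <- function(results, scheme = threshold_scheme(), unit = c("snp", "gene")) {
  unit <- match.arg(unit)
  if (!all(c("meta_p", "mega_p") %in% names(results))) {
    stop("results must have meta_p and mega_p columns", call. = FALSE)
  }
  tiers <- scheme[[unit]]
  results %>%
    dplyr::mutate(meta_tier = tier_of(.data$meta_p, tiers),
                  mega_tier = tier_of(.data$mega_p, tiers))
}

#' Count units passing a threshold in both meta- and mega-analysis
#'
#' @param results Tibble with `meta_p` and `mega_p`.
#' @param threshold Strict upper bound applied to both columns.
#' @return Integer count.
#' @export
count_suggestive <- function(results, threshold = 5e-3) {
  if (!nrow(results)) return(0L)
  sum(results$meta_p < threshold & results$mega_p < threshold, na.rm = TRUE)
}
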