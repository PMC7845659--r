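#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the allele counts, the p-value
#' is the sum of the probabilities of all heterozygote configurations that
#' are no more probable than the observed one (ties included).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required", call. = FALSE)
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het | allele counts): 2^het * n! / (hr! het! ha!) * na! nr! / (2n)!
  log_p <- hets * log(2) + lgamma(n + 1) -
    lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (rare + hets) / 2 + 1) +
    lgamma(n_alt + 1) + lgamma(2 * n - n_alt + 1) - lgamma(2 * n + 1)
  prob <- exp(log_p - max(log_p))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_het]
  if (!length(obs)) stop("heterozygote count inconsistent with allele counts", call. = FALSE)
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}

#' Per-variant quality-control statistics
#'
#' Minor allele frequency (computed on non-missing calls with minor-allele
#' orientation), genotype missing rate, genotype counts, and the exact HWE
#' p-value. Variants with zero non-missing calls get `NA` statistics and
#' are flagged.
#'
#' @param genotypes A [geno_matrix()].
#' @return Tibble with one row per variant: id, chrom, pos, n_obs,
#'   alt_freq, maf, missing_rate, n_hom_ref, n_het, n_hom_alt, hwe_p,
#'   no_calls.
#' @export
variant_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!ncol(genotypes)) stop("empty genotype matrix", call. = FALSE)
  calls <- unclass(genotypes)
  n <- nrow(calls)
  n_obs <- unname(colSums(!is.na(calls)))
  n_het <- unname(colSums(calls == 1L, na.rm = TRUE))
  n_hom_alt <- unname(colSums(calls == 2L, na.rm = TRUE))
  n_hom_ref <- n_obs - n_het - n_hom_alt
  alt_freq <- ifelse(n_obs > 0, (2 * n_hom_alt + n_het) / (2 * n_obs), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_exact_p(n_hom_ref[j], n_het[j], n_hom_alt[j])
  }, numeric(1))
  variant_info(genotypes) %>%
    dplyr::select("id", "chrom", "pos") %>%
    dplyr::mutate(n_obs = n_obs, alt_freq = alt_freq, maf = maf,
                  missing_rate = (n - n_obs) / n,
                  n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt,
                  hwe_p = hwe_p, no_calls = n_obs == 0)
}

#' Apply marker QC filters
#'
#' A variant is retained iff it passes all criteria: HWE exact p strictly
#' above `hwe_p_min`, missing rate at most `max_missing` (inclusive), and
#' MAF at least `min_maf` (inclusive). Idempotent.
#'
#' @param report Tibble from [variant_stats()].
#' @param hwe_p_min,max_missing,min_maf Thresholds (defaults 1e-4, 0.05,
#'   0.05).
#' @return List with `retained` (character ids) and `excluded` (tibble id,
#'   reason; multiple reasons joined by ";").
#' @export
filter_variants <- function(report, hwe_p_min = 1e-4, max_missing = 0.05, min_maf = 0.05) {
  reasons <- purrr::pmap_chr(
    list(report$no_calls, report$hwe_p, report$missing_rate, report$maf),
    function(nc, hp, mr, mf) {
      if (isTRUE(nc)) return("no_calls")
      r <- c(if (!is.na(hp) && hp <= hwe_p_min) "hwe",
             if (mr > max_missing) "missing",
             if (!is.na(mf) && mf < min_maf) "maf")
      if (length(r)) paste(r, collapse = ";") else NA_character_
    })
  list(retained = report$id[is.na(reasons)],
       excluded = tibble::tibble(id = report$id, reason = reasons) %>%
         dplyr::filter(!is.na(.data$reason)))
}

#' Per-sample call rate and sample filter
#'
#' @param genotypes A [geno_matrix()].
#' @return Tibble subject_id, call_rate (non-missing fraction).
#' @export
sample_call_rate <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  calls <- unclass(genotypes)
  tibble::tibble(subject_id = rownames(calls),
                 call_rate = unname(rowMeans(!is.na(calls))))
}

#' @rdname sample_call_rate
#' @param rates Tibble from `sample_call_rate()`.
#' @param min_rate Retention threshold; samples with call rate strictly
#'   greater than `min_rate` are retained (a rate of exactly 0.97 is
#'   excluded under the default).
#' @return `filter_samples()`: list with `retained` ids and `excluded`
#'   tibble (subject_id, call_rate).
#' @export
filter_samples <- function(rates, min_rate = 0.97) {
  keep <- rates$call_rate > min_rate
  list(retained = rates$subject_id[keep],
       excluded = rates[!keep, c("subject_id", "call_rate")])
}

#' Pairwise identity-by-state distance
#'
#' `distance(i, j) = 1 - (shared allele score) / (2 x shared non-missing
#' variants)`, where a variant contributes 2 - |g_i - g_j| shared alleles.
#' Pairs with no shared non-missing variant get `NA`.
#'
#' @param genotypes A [geno_matrix()] with at least 2 samples.
#' @return Symmetric matrix with zero diagonal.
#' @export
ibs_distance <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (nrow(genotypes) < 2) stop("need at least 2 samples", call. = FALSE)
  calls <- unclass(genotypes)
  O <- (!is.na(calls)) * 1
  A <- calls; A[is.na(A)] <- 0L
  storage.mode(A) <- "double"
  P <- A^2
  d2 <- P %*% t(O) + O %*% t(P) - 2 * tcrossprod(A)
  I0 <- (A == 0 & O == 1) * 1
  I2 <- (A == 2) * 1
  n02 <- I0 %*% t(I2) + I2 %*% t(I0)
  shared <- tcrossprod(O)
  sumabs <- d2 - 2 * n02
  dist <- ifelse(shared > 0, sumabs / (2 * shared), NA_real_)
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(calls), rownames(calls))
  dist
}

#' Per-sample inbreeding coefficient
#'
#' `F = 1 - observed het / expected het`, with expected heterozygosity
#' `2 p (1 - p)` summed over the sample's non-missing variants using
#' sample allele frequencies.
#'
#' @param genotypes A [geno_matrix()].
#' @return Tibble subject_id, f.
#' @export
inbreeding_coeff <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  calls <- unclass(genotypes)
  p <- colMeans(calls, na.rm = TRUE) / 2
  ehet_v <- 2 * p * (1 - p)
  O <- !is.na(calls)
  exp_het <- O %*% ehet_v
  obs_het <- unname(rowSums(calls == 1L, na.rm = TRUE))
  tibble::tibble(subject_id = rownames(calls),
                 f = ifelse(exp_het > 0, 1 - obs_het / as.numeric(exp_het), NA_real_))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS (double-centering + eigen-decomposition, via
#' `stats::cmdscale()`). `k` larger than the number of positive eigenvalues
#' is truncated with a warning.
#'
#' @param dist Symmetric distance matrix.
#' @param k Number of components (default 4).
#' @return Matrix of coordinates (samples x components).
#' @export
mds_embed <- function(dist, k = 4) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), k >= 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = min(k, nrow(dist) - 1)))
  if (ncol(fit) < k) warning("requested ", k, " components; only ", ncol(fit), " available")
  colnames(fit) <- paste0("C", seq_len(ncol(fit)))
  fit
}

#' Flag outlying samples in an MDS embedding
#'
#' A sample is an outlier if any of its first `k` coordinates lies more
#' than `mads` median absolute deviations from that component's median.
#' Components with zero MAD carry no information and are skipped.
#'
#' @param coords Matrix from [mds_embed()].
#' @param mads Threshold in MAD units (default 6).
#' @return Logical vector, one flag per sample.
#' @export
flag_outliers <- function(coords, mads = 6) {
  flags <- rep(FALSE, nrow(coords))
  for (j in seq_len(ncol(coords))) {
    x <- coords[, j]
    s <- stats::mad(x)
    if (s > 0) flags <- flags | (abs(x - stats::median(x)) > mads * s)
  }
  flags
}

#' Drop one member of each closely related sample pair
#'
#' Pairs with IBS distance below `max_dist` are treated as kin; the member
#' with the lower call rate is excluded.
#'
#' @param dist IBS distance matrix.
#' @param rates Tibble from [sample_call_rate()].
#' @param max_dist Kinship distance threshold (default 0.1).
#' @return List with `retained` ids and `excluded` tibble (subject_id,
#'   reason).
#' @export
kinship_filter <- function(dist, rates, max_dist = 0.1) {
  ids <- rownames(dist)
  cr <- rates$call_rate[match(ids, rates$subject_id)]
  dropped <- character()
  pairs <- which(upper.tri(dist) & !is.na(dist) & dist < max_dist, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(dist[pairs])
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (ids[i] %in% dropped || ids[j] %in% dropped) next
      dropped <- c(dropped, if (cr[i] <= cr[j]) ids[i] else ids[j])
    }
  }
  list(retained = setdiff(ids, dropped),
       excluded = tibble::tibble(subject_id = dropped, reason = "kinship"))
}
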