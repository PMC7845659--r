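#' Map variants into a flanked gene region
#'
#' A variant is mapped iff `start - flank <= pos <= end + flank`, with
#' 1-based inclusive coordinates on both sides.
#'
#' @param variants Variant tibble (e.g. [variant_info()]).
#' @param region One-row gene region (gene_id, chrom, start, end).
#' @param flank Flank size in bp (default 50 kb).
#' @return Integer indices into `variants`.
#' @export
map_variants <- function(variants, region, flank = 50000) {
  which(variants$chrom == region$chrom &
          variants$pos >= region$start - flank &
          variants$pos <= region$end + flank)
}

#' Composite LD between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete subjects.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors.
#' @return r-squared in \[0, 1\], or `NA` if either vector has zero
#'   variance on the complete pairs.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(keep) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  a <- dosage_a[keep]; b <- dosage_b[keep]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Greedy LD pruning in position order
#'
#' Scans mapped variants in ascending position order and retains a variant
#' iff its r-squared with every already-retained variant is strictly below
#' `r2_max`. Phenotype-independent and deterministic, so the retained set
#' is identical across permutations. Zero-variance variants are dropped.
#'
#' @param genotypes A [geno_matrix()].
#' @param mapped Integer indices of the mapped variants.
#' @param r2_max Pruning threshold (default 0.5).
#' @return Integer indices of the retained variants (subset of `mapped`).
#' @export
prune_ld <- function(genotypes, mapped, r2_max = 0.5) {
  if (!length(mapped)) stop("no mapped variants to prune", call. = FALSE)
  vi <- variant_info(genotypes)
  calls <- unclass(genotypes)
  ord <- mapped[order(vi$pos[mapped])]
  retained <- integer()
  for (j in ord) {
    g <- as.numeric(calls[, j])
    if (isTRUE(stats::var(g, na.rm = TRUE) %in% c(0, NA))) next
    ok <- TRUE
    for (k in retained) {
      r2 <- ld_r2(g, as.numeric(calls[, k]))
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, j)
  }
  retained
}

#' Truncated-Fisher gene statistic
#'
#' Sums `-2 ln p` over the marker p-values below the entry threshold;
#' zero when no marker qualifies.
#'
#' @param p_values Marker p-values in (0, 1] (`NA` entries are skipped).
#' @param p_enter Entry threshold (default 0.1).
#' @return The statistic T >= 0.
#' @export
gene_statistic <- function(p_values, p_enter = 0.1) {
  p <- p_values[!is.na(p_values)]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  keep <- p < p_enter
  if (!any(keep)) return(0)
  sum(-2 * log(p[keep]))
}

# Dosage matrix for a variant set: minor-allele oriented, per-variant
# mean imputation of missing calls (synthetic data is complete; this
# only matters for user-supplied genotypes).
dosage_matrix <- function(genotypes, idx) {
  G <- unclass(genotypes)[, idx, drop = FALSE]
  storage.mode(G) <- "double"
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  G[, flip] <- 2 - G[, flip]
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  G
}

#' Permutation-based gene-level association test
#'
#' Computes the observed truncated-Fisher statistic over the gene's
#' LD-pruned markers, then draws the null by permuting the subject labels
#' of the genotype block while keeping phenotype-covariate pairs fixed:
#' marker-marker LD is preserved exactly in every permutation (this is the
#' LD correction), marker p-values are recomputed and the entry threshold
#' re-applied inside each permutation. The empirical p-value is
#' `(1 + #\{T_perm >= T_obs\}) / (K + 1)`; ties count as exceedances.
#'
#' @param genotypes A [geno_matrix()] (QC-passed variants).
#' @param data Phenotype tibble with `subject_id`, outcome, covariates.
#' @param outcome Outcome column name.
#' @param region One-row gene region tibble.
#' @param covariates Covariate column names (default age + sex).
#' @param family `"linear"` or `"logistic"`.
#' @param K Number of permutations (default 50,000).
#' @param p_enter Marker entry threshold (default 0.1).
#' @param r2_max LD pruning threshold (default 0.5).
#' @param flank Region flank in bp (default 50 kb).
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble: gene_id, n_mapped, n_retained, n_contributing,
#'   prop_sig (markers with p < 0.05 over mapped markers), t_obs,
#'   n_perm, n_exceed, empirical_p.
#' @export
gene_empirical_p <- function(genotypes, data, outcome, region,
                             covariates = c("age", "sex"),
                             family = c("linear", "logistic"),
                             K = 50000, p_enter = 0.1, r2_max = 0.5,
                             flank = 50000, seed = 1L) {
  family <- match.arg(family)
  vi <- variant_info(genotypes)
  mapped <- map_variants(vi, region, flank = flank)
  if (!length(mapped)) {
    return(tibble::tibble(gene_id = region$gene_id, n_mapped = 0L,
                          n_retained = 0L, n_contributing = 0L,
                          prop_sig = NA_real_, t_obs = NA_real_,
                          n_perm = 0L, n_exceed = NA_integer_,
                          empirical_p = NA_real_, skipped = TRUE))
  }
  idx <- match(rownames(genotypes), data$subject_id)
  y_raw <- data[[outcome]][idx]
  y <- if (family == "logistic") as_event(y_raw) else as.numeric(y_raw)
  cf <- covariate_frame(data, covariates)[idx, , drop = FALSE]
  keep <- !is.na(y) & stats::complete.cases(cf)
  y <- y[keep]; cf <- cf[keep, , drop = FALSE]
  X <- if (ncol(cf)) stats::model.matrix(~ ., data = cf) else
    matrix(1, length(y), 1)
  if (length(y) <= ncol(X) + 1) stop("fewer complete cases than covariates", call. = FALSE)
  gsub_ <- geno_subset(genotypes, subjects = which(keep))
  retained <- prune_ld(gsub_, mapped, r2_max = r2_max)
  engine <- marker_engine(y, X, family)
  G_mapped <- dosage_matrix(gsub_, mapped)
  p_mapped <- engine$pvals(G_mapped)
  prop_sig <- mean(p_mapped < 0.05, na.rm = TRUE)
  if (!length(retained)) {
    return(tibble::tibble(gene_id = region$gene_id, n_mapped = length(mapped),
                          n_retained = 0L, n_contributing = 0L,
                          prop_sig = prop_sig, t_obs = NA_real_,
                          n_perm = 0L, n_exceed = NA_integer_,
                          empirical_p = NA_real_, skipped = TRUE))
  }
  G <- dosage_matrix(gsub_, retained)
  p_obs <- engine$pvals(G)
  t_obs <- gene_statistic(p_obs[!is.na(p_obs)], p_enter = p_enter)
  n <- length(y)
  set.seed(derive_seed(seed, paste0("gene", region$gene_id)))
  exceed <- 0L
  for (b in seq_len(K)) {
    Gp <- G[sample.int(n), , drop = FALSE]
    pp <- engine$pvals(Gp)
    tp <- gene_statistic(pp[!is.na(pp)], p_enter = p_enter)
    if (tp >= t_obs) exceed <- exceed + 1L
  }
  tibble::tibble(gene_id = region$gene_id, n_mapped = length(mapped),
                 n_retained = length(retained),
                 n_contributing = sum(p_obs < p_enter, na.rm = TRUE),
                 prop_sig = prop_sig, t_obs = t_obs,
                 n_perm = as.integer(K), n_exceed = exceed,
                 empirical_p = (exceed + 1) / (K + 1), skipped = FALSE)
}

#' Gene-level association scan over a region table
#'
#' Runs [gene_empirical_p()] per region; genes mapping no variant are
#' reported with `skipped = TRUE`.
#'
#' @inheritParams gene_empirical_p
#' @param regions Gene region tibble (gene_id, chrom, start, end).
#' @return Tibble with one row per gene.
#' @export
gene_scan <- function(genotypes, data, outcome, regions,
                      covariates = c("age", "sex"),
                      family = c("linear", "logistic"),
                      K = 50000, p_enter = 0.1, r2_max = 0.5,
                      flank = 50000, seed = 1L) {
  family <- match.arg(family)
  if (!nrow(regions)) {
    return(tibble::tibble(gene_id = character(), n_mapped = integer(),
                          n_retained = integer(), n_contributing = integer(),
                          prop_sig = numeric(), t_obs = numeric(),
                          n_perm = integer(), n_exceed = integer(),
                          empirical_p = numeric(), skipped = logical()))
  }
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    gene_empirical_p(genotypes, data, outcome, regions[i, ],
                     covariates = covariates, family = family, K = K,
                     p_enter = p_enter, r2_max = r2_max, flank = flank,
                     seed = derive_seed(seed, regions$gene_id[i]))
  })
}
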