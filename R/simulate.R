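#' HRSD-21 item score maxima
#'
#' Per-item maximum scores used by the generator and by range validation.
#' Ten items (including item 1, "depressed mood") are rated 0-4; the
#' remaining eleven are rated 0-2, for a scale maximum of 62.
#'
#' @return Integer vector of length 21.
#' @export
hrsd_item_max <- function() {
  mx <- rep(2L, 21)
  mx[c(1, 2, 3, 7, 8, 9, 10, 11, 15, 19)] <- 4L
  mx
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic two-cohort trial generator. The
#' defaults describe the study conditions the pipeline is exercised under:
#' two cohorts of 253 and 175 subjects with different sex and age mixes,
#' LD-block genotypes with minor allele frequencies in 0.05-0.5, HRSD-21
#' trajectories calibrated so that roughly a third of subjects remit by
#' week 8 and close to 39% respond by week 4, and visit-level missingness
#' with a 92% / 7% / 1% complete / one-missing / two-plus-missing split.
#'
#' @param n_subjects Named integer vector, subjects per cohort.
#' @param n_variants Number of simulated variants.
#' @param block_size Variants per LD block (last block may be smaller).
#' @param block_cor Latent within-block haplotype correlation in `[0, 1]`.
#' @param maf_range Target minor-allele-frequency range, a sub-interval of
#'   `(0, 0.5]`. One target frequency is drawn per block.
#' @param causal Optional tibble with columns `id` and `effect`: per-allele
#'   additive effect of each causal variant on the weekly decline rate
#'   (HRSD points per unit of the week scale; negative = faster
#'   improvement).
#' @param sex_male_frac,age_mean,age_sd Named per-cohort demography.
#' @param baseline_mean,baseline_sd Baseline HRSD total distribution
#'   (truncated at the trial floor of 14 and the scale maximum).
#' @param decline_mean,decline_sd Per-subject latent decline rate
#'   distribution (HRSD points per unit week-scale).
#' @param week_scale Named numeric, the nonlinear time scale `s(w)` at
#'   weeks 0/2/4/8; weekly totals follow `baseline + d_i * s(w) + noise`.
#' @param noise_sd Visit-level noise s.d. (HRSD points), weeks > 0 only.
#' @param item1_weight Allocation weight of item 1 relative to weight-1
#'   items; controls how much of the total lands on "depressed mood".
#' @param miss_probs Named probabilities `complete`, `one`, `twoplus` for
#'   the per-subject count of missing post-baseline visits.
#' @param drugs Character vector of drug labels sampled per subject.
#' @param seed Integer seed fixing all stochastic output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = c(A = 253, B = 175),
                       n_variants = 60,
                       block_size = 5,
                       block_cor = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal = NULL,
                       sex_male_frac = c(A = 0.174, B = 0.451),
                       age_mean = c(A = 41.0, B = 47.4),
                       age_sd = c(A = 13.7, B = 15.1),
                       baseline_mean = 22,
                       baseline_sd = 3,
                       decline_mean = -2.25,
                       decline_sd = 0.6,
                       week_scale = c(`0` = 0, `2` = 3.68, `4` = 4.35, `8` = 5.5),
                       noise_sd = 1.5,
                       item1_weight = 3.8,
                       miss_probs = c(complete = 0.92, one = 0.07, twoplus = 0.01),
                       drugs = c("escitalopram", "paroxetine", "fluoxetine", "citalopram"),
                       seed = 1L) {
  if (any(n_subjects <= 0) || n_variants <= 0) {
    stop("subject and variant counts must be positive", call. = FALSE)
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be a non-empty sub-interval of (0, 0.5]", call. = FALSE)
  }
  assert_prob(block_cor, "block_cor")
  assert_prob(miss_probs, "miss_probs")
  if (abs(sum(miss_probs) - 1) > 1e-8) {
    stop("miss_probs must sum to 1", call. = FALSE)
  }
  if (!is.null(causal)) causal <- tibble::as_tibble(causal)
  structure(
    list(n_subjects = n_subjects, n_variants = n_variants,
         block_size = block_size, block_cor = block_cor,
         maf_range = maf_range, causal = causal,
         sex_male_frac = sex_male_frac, age_mean = age_mean, age_sd = age_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         decline_mean = decline_mean, decline_sd = decline_sd,
         week_scale = week_scale, noise_sd = noise_sd,
         item1_weight = item1_weight, miss_probs = miss_probs,
         drugs = drugs, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate LD-block genotypes
#'
#' Draws two haplotypes per subject from a block-correlated latent Gaussian
#' pool: within a block every variant shares one target allele frequency
#' and its haplotype alleles are thresholded from an equicorrelated
#' Gaussian (correlation `block_cor`), so pairwise r-squared within a block
#' is tunable and a correlation of 1 makes the block's call vectors
#' identical. Blocks are mutually independent.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with `sum(config$n_subjects)` subjects.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- sum(config$n_subjects)
  m <- config$n_variants
  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$block_size))
  rho <- config$block_cor
  calls <- matrix(0L, n, m)
  block_f <- stats::runif(length(blocks), config$maf_range[1], config$maf_range[2])
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    thr <- stats::qnorm(block_f[b])
    hap <- matrix(0L, 2 * n, length(idx))
    z0 <- stats::rnorm(2 * n)
    for (j in seq_along(idx)) {
      z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(2 * n)
      hap[, j] <- as.integer(z < thr)
    }
    calls[, idx] <- hap[seq_len(n), , drop = FALSE] +
      hap[n + seq_len(n), , drop = FALSE]
  }
  pos <- 47200000L + cumsum(sample(400:2500, m, replace = TRUE))
  alleles <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2), character(2)))
  variants <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(m)), chrom = "13", pos = pos,
    ref = alleles[, 1], alt = alleles[, 2],
    is_chip = seq_len(m) %% 5 == 1
  )
  subjects <- sprintf("%s%04d", rep(names(config$n_subjects), config$n_subjects),
                      unlist(lapply(config$n_subjects, seq_len)))
  geno_matrix(calls, variants, subjects = subjects)
}

# Distribute an integer total over the 21 items by largest-remainder
# proportional allocation against fixed weights, capped at item maxima.
allocate_items <- function(total, item1_weight) {
  mx <- hrsd_item_max()
  total <- min(max(total, 0L), sum(mx))
  w <- c(item1_weight, rep(1, 20))
  ideal <- total * w / sum(w)
  alloc <- pmin(floor(ideal), mx)
  left <- total - sum(alloc)
  while (left > 0) {
    deficit <- ifelse(alloc < mx, ideal - alloc, -Inf)
    k <- which.max(deficit)
    alloc[k] <- alloc[k] + 1
    left <- left - 1
  }
  as.integer(alloc)
}

#' Simulate an SSRI trial on top of simulated genotypes
#'
#' Each subject gets a baseline HRSD-21 total of at least 14 and weekly
#' totals `baseline + d_i * s(w) + noise`, where the subject's latent
#' decline rate `d_i` is Gaussian plus an additive causal-dosage effect.
#' Totals are rounded, clamped to the scale range, and spread over the 21
#' items by weighted largest-remainder allocation so that item totals are
#' exact and item 1 severity is controllable.
#'
#' @param genotypes A [geno_matrix()] covering the requested subjects.
#' @param config A [sim_config()].
#' @return A list with `subjects` (tibble: subject_id, cohort, sex, age,
#'   drug) and `panel` (HRSD panel tibble: subject_id, week,
#'   item01..item21; one row per subject-week).
#' @export
simulate_trial <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(derive_seed(config$seed, "trial"))
  n_per <- config$n_subjects
  n <- sum(n_per)
  if (nrow(genotypes) < n) stop("genotype matrix does not cover the requested subjects", call. = FALSE)
  ids <- subject_ids(genotypes)[seq_len(n)]
  cohort <- rep(names(n_per), n_per)

  sex <- unlist(lapply(names(n_per), function(cc) {
    ifelse(stats::runif(n_per[[cc]]) < config$sex_male_frac[[cc]], "male", "female")
  }))
  age <- unlist(lapply(names(n_per), function(cc) {
    pmax(18, round(stats::rnorm(n_per[[cc]], config$age_mean[[cc]], config$age_sd[[cc]])))
  }))
  drug <- sample(config$drugs, n, replace = TRUE)
  subjects <- tibble::tibble(subject_id = ids, cohort = cohort, sex = sex,
                             age = age, drug = drug)

  scale_max <- sum(hrsd_item_max())
  baseline <- round(stats::rnorm(n, config$baseline_mean, config$baseline_sd))
  baseline <- pmin(pmax(baseline, 14L), 40L)

  decline <- stats::rnorm(n, config$decline_mean, config$decline_sd)
  if (!is.null(config$causal) && nrow(config$causal)) {
    miss <- setdiff(config$causal$id, variant_info(genotypes)$id)
    if (length(miss)) stop("causal variant(s) absent from genotypes: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    for (k in seq_len(nrow(config$causal))) {
      g <- unclass(genotypes)[seq_len(n), config$causal$id[k]]
      decline <- decline + config$causal$effect[k] * g
    }
  }

  weeks <- c(0L, 2L, 4L, 8L)
  sw <- config$week_scale[as.character(weeks)]
  rows <- vector("list", length(weeks))
  for (wi in seq_along(weeks)) {
    if (weeks[wi] == 0L) {
      tot <- baseline
    } else {
      tot <- round(baseline + decline * sw[wi] + stats::rnorm(n, 0, config$noise_sd))
      tot <- pmin(pmax(tot, 0L), scale_max)
    }
    items <- t(vapply(tot, allocate_items, integer(21), item1_weight = config$item1_weight))
    colnames(items) <- sprintf("item%02d", 1:21)
    rows[[wi]] <- tibble::tibble(subject_id = ids, week = weeks[wi]) %>%
      dplyr::bind_cols(tibble::as_tibble(items))
  }
  panel <- dplyr::bind_rows(rows) %>% dplyr::arrange(.data$subject_id, .data$week)
  list(subjects = subjects, panel = panel)
}

#' Remove visits to emulate trial missingness
#'
#' Per subject, draws how many post-baseline visits are missing (none, one,
#' or two) with the configured probabilities and blanks the item scores of
#' the chosen weeks. The baseline visit is never removed.
#'
#' @param panel HRSD panel tibble from [simulate_trial()].
#' @param config A [sim_config()]; `miss_probs` must sum to 1.
#' @return The panel with removed visits' item columns set to `NA`.
#' @export
inject_missingness <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "missingness"))
  p <- config$miss_probs[c("complete", "one", "twoplus")]
  if (anyNA(p) || abs(sum(p) - 1) > 1e-8) stop("miss_probs must sum to 1", call. = FALSE)
  ids <- unique(panel$subject_id)
  n_miss <- sample(c(0L, 1L, 2L), length(ids), replace = TRUE, prob = p)
  drop <- purrr::map2(ids, n_miss, function(id, k) {
    if (k == 0L) return(NULL)
    tibble::tibble(subject_id = id, week = sample(c(2L, 4L, 8L), k))
  })
  drop <- dplyr::bind_rows(drop)
  if (!nrow(drop)) return(panel)
  item_cols <- sprintf("item%02d", 1:21)
  hit <- paste(panel$subject_id, panel$week) %in% paste(drop$subject_id, drop$week)
  panel[hit, item_cols] <- NA_integer_
  panel
}
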