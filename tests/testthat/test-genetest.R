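test_that("variant-to-gene mapping uses inclusive 50 kb flank boundaries", {
  variants <- tibble::tibble(
    id = paste0("v", 1:5), chrom = "13",
    pos = c(950000L, 949999L, 1200000L, 1250000L, 1250001L),
    ref = "A", alt = "G")
  region <- tibble::tibble(gene_id = "G1", chrom = "13",
                           start = 1000000L, end = 1200000L)
  idx <- map_variants(variants, region)
  expect_equal(idx, c(1, 3, 4))   # start - 50k inclusive, end + 50k inclusive
  region2 <- region; region2$chrom <- "14"
  expect_equal(length(map_variants(variants, region2)), 0)

  # constructed gene: 7 in-window, 3 out-of-window
  v10 <- tibble::tibble(id = paste0("w", 1:10), chrom = "13",
                        pos = c(seq(960000, 1240000, length.out = 7),
                                900000, 1300000, 2000000),
                        ref = "A", alt = "G")
  expect_equal(length(map_variants(v10, region)), 7)
})

test_that("dosage r-squared is symmetric, flip-invariant, and null-calibrated", {
  set.seed(3)
  a <- rbinom(1000, 2, 0.3)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  r2s <- replicate(300, ld_r2(a, rbinom(1000, 2, 0.3)))
  # null squared correlation has mean ~ 1/(n-1)
  se <- sd(r2s) / sqrt(300)
  expect_lt(abs(mean(r2s) - 1 / 999), 3 * se)
  expect_true(is.na(ld_r2(a, rep(1, 1000))))
  expect_error(ld_r2(1, 1), "complete pairs")
})

test_that("LD pruning keeps one variant per tight block, scanning by position", {
  cfg <- sim_config(n_subjects = c(A = 300, B = 300), n_variants = 15,
                    block_size = 5, block_cor = 0.98, seed = 17)
  g <- simulate_genotypes(cfg)
  kept <- prune_ld(g, seq_len(15), r2_max = 0.5)
  blocks <- ceiling(kept / 5)
  expect_equal(length(kept), 3)
  expect_equal(sort(unique(blocks)), 1:3)

  # duplicated variant: only the first by position survives
  calls <- cbind(rbinom(100, 2, 0.3), 0L)
  calls[, 2] <- calls[, 1]
  gd <- geno_matrix(calls, tibble::tibble(id = c("first", "second"), chrom = "1",
                                          pos = c(10L, 20L), ref = "A", alt = "G"))
  expect_equal(prune_ld(gd, 1:2), 1)

  # independent variants: everything survives
  gi <- make_geno(400, 10, maf = 0.3, seed = 2)
  expect_equal(prune_ld(gi, 1:10), 1:10)
})

test_that("the truncated-Fisher gene statistic matches its closed form", {
  expect_equal(gene_statistic(c(0.5, 0.2, 0.99)), 0)
  expect_equal(gene_statistic(0.01), -2 * log(0.01))
  expect_equal(round(gene_statistic(0.01), 4), 9.2103)
  expect_equal(gene_statistic(c(0.05, 0.5)), -2 * log(0.05))
  expect_equal(round(gene_statistic(c(0.05, 0.5)), 4), 5.9915)
  expect_error(gene_statistic(c(0.5, 0)), "p-values")
})

test_that("single-SNP gene empirical p matches a marker-level permutation oracle", {
  set.seed(44)
  n <- 250
  g <- make_geno(n, 1, maf = 0.3, seed = 44)
  data <- tibble::tibble(subject_id = rownames(g),
                         age = rnorm(n, 45, 10),
                         sex = sample(c("male", "female"), n, TRUE))
  dose <- as.numeric(unclass(g)[, 1])
  data$y <- 0.25 * dose + rnorm(n)
  region <- tibble::tibble(gene_id = "G", chrom = "13",
                           start = min(variant_info(g)$pos),
                           end = max(variant_info(g)$pos))
  K <- 1999
  res <- gene_empirical_p(g, data, "y", region, family = "linear", K = K, seed = 5)
  expect_equal(res$n_retained, 1L)

  # independent oracle: permute the dosage, refit with lm, count p <= p_obs
  cf <- data.frame(age = data$age, sex = factor(data$sex))
  p_of <- function(d) summary(lm(data$y ~ d + cf$age + cf$sex))$coefficients[2, 4]
  p_obs <- p_of(dose)
  set.seed(99)
  p_perm <- replicate(K, p_of(sample(dose)))
  oracle <- (1 + sum(p_perm <= p_obs)) / (K + 1)
  mc_err <- 3 * sqrt(oracle * (1 - oracle) / K)
  expect_lt(abs(res$empirical_p - oracle), mc_err + 2 / (K + 1))
})

test_that("empty-signal genes give empirical p near 1 and bounds hold", {
  set.seed(50)
  n <- 200
  g <- make_geno(n, 5, maf = 0.3, seed = 50)
  data <- tibble::tibble(subject_id = rownames(g), age = rnorm(n, 45, 10),
                         sex = sample(c("male", "female"), n, TRUE),
                         y = rnorm(n))
  region <- tibble::tibble(gene_id = "G", chrom = "13",
                           start = min(variant_info(g)$pos),
                           end = max(variant_info(g)$pos))
  res <- gene_empirical_p(g, data, "y", region, family = "linear", K = 199, seed = 8)
  expect_gte(res$empirical_p, 1 / 200)
  expect_lte(res$empirical_p, 1)
  if (res$t_obs == 0) expect_gt(res$empirical_p, 0.5)

  # no variant maps -> skipped row, and gene_scan mirrors per-gene calls
  far <- tibble::tibble(gene_id = "far", chrom = "13",
                        start = 99000000L, end = 99100000L)
  sk <- gene_empirical_p(g, data, "y", far, family = "linear", K = 99, seed = 8)
  expect_true(sk$skipped)
  both <- gene_scan(g, data, "y", dplyr::bind_rows(region, far),
                    family = "linear", K = 199, seed = 8)
  expect_equal(nrow(both), 2)
  expect_true(both$skipped[2])
  expect_equal(nrow(gene_scan(g, data, "y", region[0, ], family = "linear")), 0)
})

test_that("gene test reruns identically under the same seed and reports Prop", {
  set.seed(60)
  n <- 150
  g <- make_geno(n, 8, maf = 0.3, seed = 60)
  data <- tibble::tibble(subject_id = rownames(g), age = rnorm(n, 45, 10),
                         sex = sample(c("male", "female"), n, TRUE), y = rnorm(n))
  region <- tibble::tibble(gene_id = "G", chrom = "13",
                           start = min(variant_info(g)$pos),
                           end = max(variant_info(g)$pos))
  r1 <- gene_empirical_p(g, data, "y", region, family = "linear", K = 299, seed = 21)
  r2 <- gene_empirical_p(g, data, "y", region, family = "linear", K = 299, seed = 21)
  expect_identical(r1, r2)
  expect_equal(r1$n_mapped, 8L)
  expect_true(r1$prop_sig >= 0 && r1$prop_sig <= 1)
})
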