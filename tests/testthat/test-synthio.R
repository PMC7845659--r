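test_that("genotype simulation is deterministic and honours the block model", {
  cfg <- sim_config(n_subjects = c(A = 40, B = 30), n_variants = 20, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(unclass(g1), unclass(g2))

  # perfect within-block correlation forces identical call vectors
  cfg1 <- sim_config(n_subjects = c(A = 50, B = 50), n_variants = 6,
                     block_size = 3, block_cor = 1, seed = 3)
  g <- simulate_genotypes(cfg1)
  calls <- unclass(g)
  expect_identical(calls[, 1], calls[, 2])
  expect_identical(calls[, 2], calls[, 3])
  expect_identical(calls[, 4], calls[, 6])

  expect_error(sim_config(n_subjects = c(A = 0, B = 10)), "positive")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
})

test_that("realized allele frequency matches the binomial sampling oracle", {
  cfg <- sim_config(n_subjects = c(A = 500, B = 500), n_variants = 40,
                    block_size = 1, maf_range = c(0.3, 0.3), seed = 5)
  g <- simulate_genotypes(cfg)
  af <- colMeans(unclass(g)) / 2
  se_mean <- sqrt(0.3 * 0.7 / (2 * 1000)) / sqrt(40)
  expect_lt(abs(mean(af) - 0.3), 3 * se_mean)
})

test_that("degenerate trial dynamics keep every visit at baseline", {
  cfg <- sim_config(n_subjects = c(A = 30, B = 20), n_variants = 4,
                    decline_mean = 0, decline_sd = 0, noise_sd = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trial(g, cfg)
  items <- sprintf("item%02d", 1:21)
  totals <- tr$panel %>%
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(items)))) %>%
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "week", values_from = "total")
  expect_true(all(totals$`2` == totals$`0`))
  expect_true(all(totals$`8` == totals$`0`))
  expect_true(all(totals$`0` >= 14))
})

test_that("a strong causal dosage effect shifts week-8 severity by genotype group", {
  cfg <- sim_config(n_subjects = c(A = 400, B = 400), n_variants = 6,
                    block_size = 1, maf_range = c(0.4, 0.5),
                    causal = tibble::tibble(id = "snp0002", effect = -0.8), seed = 9)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trial(g, cfg)
  ph <- build_phenotypes(tr$panel, tr$subjects)
  dose <- unclass(g)[, "snp0002"]
  m0 <- mean(ph$week8_total[dose == 0])
  m2 <- mean(ph$week8_total[dose == 2])
  expect_lt(m2, m0)
  expect_error(simulate_trial(g, sim_config(n_subjects = cfg$n_subjects, n_variants = 6,
                                            causal = tibble::tibble(id = "nope", effect = 1))),
               "absent")
})

test_that("default generator hits the target week-8 remission fraction", {
  cfg <- sim_config(n_subjects = c(A = 1000, B = 1000), n_variants = 4, seed = 77)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trial(g, cfg)
  ph <- build_phenotypes(tr$panel, tr$subjects)
  rem8 <- mean(ph$remitted_code == 2)
  expect_lt(abs(rem8 - 0.33), 0.05)
})

test_that("missingness injection preserves baseline and matches configured pattern rates", {
  cfg <- sim_config(n_subjects = c(A = 40, B = 20), n_variants = 4, seed = 4)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trial(g, cfg)

  cfg_none <- sim_config(n_subjects = cfg$n_subjects, n_variants = 4, seed = 4,
                         miss_probs = c(complete = 1, one = 0, twoplus = 0))
  expect_identical(inject_missingness(tr$panel, cfg_none), tr$panel)

  cfg_one <- sim_config(n_subjects = cfg$n_subjects, n_variants = 4, seed = 4,
                        miss_probs = c(complete = 0, one = 1, twoplus = 0))
  p1 <- inject_missingness(tr$panel, cfg_one)
  miss_per_subj <- p1 %>%
    dplyr::mutate(miss = is.na(.data$item01)) %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::summarise(n_miss = sum(.data$miss), wk0 = .data$miss[.data$week == 0])
  expect_true(all(miss_per_subj$n_miss == 1))
  expect_false(any(miss_per_subj$wk0))

  big <- sim_config(n_subjects = c(A = 2500, B = 2500), n_variants = 2, seed = 12)
  gb <- simulate_genotypes(big)
  trb <- simulate_trial(gb, big)
  pb <- inject_missingness(trb$panel, big)
  complete_frac <- pb %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::summarise(all_obs = !any(is.na(.data$item01))) %>%
    dplyr::pull(.data$all_obs) %>% mean()
  se <- sqrt(0.92 * 0.08 / 5000)
  expect_lt(abs(complete_frac - 0.92), 3 * se)
})

test_that("PLINK bed/bim/fam round-trip is exact, including missing calls", {
  g <- geno_matrix(matrix(c(0L, 1L, 2L, NA, 2L, 0L), 3, 2),
                   tibble::tibble(id = c("a", "b"), chrom = "13",
                                  pos = c(100L, 200L), ref = "A", alt = "G"),
                   subjects = c("s1", "s2", "s3"))
  pre <- file.path(tempdir(), "tiny")
  write_plink(g, pre)
  back <- read_plink(pre)
  expect_identical(unclass(back)[, ], unclass(g)[, ])
  expect_identical(variant_info(back)$pos, variant_info(g)$pos)

  big <- make_geno(50, 200, seed = 42, missing = 0.03)
  pre2 <- file.path(tempdir(), "big")
  write_plink(big, pre2)
  back2 <- read_plink(pre2)
  expect_identical(unclass(back2)[, ], unclass(big)[, ])
  # re-writing the read-back panel reproduces the bed bytes exactly
  pre3 <- file.path(tempdir(), "big2")
  write_plink(back2, pre3)
  expect_identical(readBin(paste0(pre2, ".bed"), "raw", 1e6),
                   readBin(paste0(pre3, ".bed"), "raw", 1e6))

  bad <- file.path(tempdir(), "bad")
  file.copy(paste0(pre, ".bim"), paste0(bad, ".bim"), overwrite = TRUE)
  file.copy(paste0(pre, ".fam"), paste0(bad, ".fam"), overwrite = TRUE)
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(bad, ".bed"))
  expect_error(read_plink(bad), "magic")
})

test_that("HRSD and phenotype TSV round-trips preserve missing values", {
  cfg <- sim_config(n_subjects = c(A = 30, B = 20), n_variants = 2, seed = 6)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trial(g, cfg)
  panel <- inject_missingness(tr$panel, cfg)
  path <- file.path(tempdir(), "panel.tsv")
  write_hrsd(panel, tr$subjects, path)
  back <- read_hrsd(path)
  expect_equal(as.data.frame(back$panel), as.data.frame(panel))
  expect_equal(nrow(back$subjects), 50)

  ph <- build_phenotypes(panel, tr$subjects)
  path2 <- file.path(tempdir(), "pheno.tsv")
  write_phenotypes(ph, path2)
  back2 <- read_phenotypes(path2)
  expect_equal(as.data.frame(back2), as.data.frame(ph))

  hdr <- file.path(tempdir(), "empty.tsv")
  writeLines(paste(c("subject_id", "cohort", "sex", "age", "week",
                     sprintf("item%02d", 1:21)), collapse = "\t"), hdr)
  empty <- read_hrsd(hdr)
  expect_equal(nrow(empty$panel), 0)

  bad <- file.path(tempdir(), "badcol.tsv")
  writeLines("subject_id\tcohort\tsex\tage\tweek\tmystery", bad)
  expect_error(read_hrsd(bad), "unknown column")
})
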