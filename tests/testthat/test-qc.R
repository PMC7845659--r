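test_that("exact HWE p equals enumeration for small tables and is symmetric", {
  expect_equal(hwe_exact_p(20, 0, 0), 1)
  expect_equal(hwe_exact_p(5, 7, 3), hwe_exact_p(3, 7, 5))
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
  for (n in c(5, 13, 27, 41)) {
    for (ha in 0:min(n, 8)) {
      for (het in 0:(n - ha)) {
        hr <- n - ha - het
        expect_equal(hwe_exact_p(hr, het, ha), hwe_oracle(hr, het, ha),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("variant statistics match direct counting", {
  g <- geno_matrix(matrix(c(1L, 1L, 1L, 1L,  0L, 0L, 1L, 2L,  NA, 0L, 1L, 2L), 4, 3),
                   tibble::tibble(id = c("a", "b", "c"), chrom = "1",
                                  pos = 1:3, ref = "A", alt = "G"))
  st <- variant_stats(g)
  expect_equal(st$maf[1], 0.5)
  expect_equal(st$alt_freq[2], 3 / 8)
  expect_equal(st$maf[2], 0.375)
  expect_equal(st$missing_rate, c(0, 0, 0.25))

  sim <- make_geno(500, 100, maf = 0.2, seed = 3, missing = 0.02)
  st2 <- variant_stats(sim)
  calls <- unclass(sim)
  for (j in c(1, 17, 100)) {
    v <- calls[, j][!is.na(calls[, j])]
    expect_equal(st2$alt_freq[j], sum(v) / (2 * length(v)))
    expect_equal(st2$missing_rate[j], mean(is.na(calls[, j])))
  }
})

test_that("variant filtering applies inclusive/strict boundaries and is idempotent", {
  report <- tibble::tibble(
    id = sprintf("v%02d", 1:10), chrom = "1", pos = 1:10, n_obs = 100,
    alt_freq = 0.2,
    maf = c(0.049, 0.05, rep(0.2, 8)),
    missing_rate = c(0, 0, 0.05, 0.051, rep(0, 6)),
    n_hom_ref = 60, n_het = 30, n_hom_alt = 10,
    hwe_p = c(rep(0.5, 4), 1e-4, 1.1e-4, rep(0.5, 4)),
    no_calls = c(rep(FALSE, 9), TRUE)
  )
  flt <- filter_variants(report)
  expect_equal(length(flt$retained), 6)
  expect_equal(flt$excluded$reason[flt$excluded$id == "v01"], "maf")
  expect_true("v02" %in% flt$retained)       # MAF exactly 0.05 retained
  expect_true("v03" %in% flt$retained)       # missing rate exactly 0.05 retained
  expect_false("v04" %in% flt$retained)
  expect_false("v05" %in% flt$retained)      # HWE p exactly 1e-4 excluded (strict >)
  expect_true("v06" %in% flt$retained)
  expect_equal(flt$excluded$reason[flt$excluded$id == "v10"], "no_calls")
  # idempotence on the surviving subset
  flt2 <- filter_variants(report[report$id %in% flt$retained, ])
  expect_equal(flt2$retained, flt$retained)
})

test_that("sample call-rate filter is strictly greater-than", {
  calls <- matrix(0L, 3, 100)
  calls[2, 1:3] <- NA    # call rate exactly 0.97
  calls[3, 1:10] <- NA
  g <- geno_matrix(calls, tibble::tibble(id = sprintf("v%03d", 1:100), chrom = "1",
                                         pos = 1:100, ref = "A", alt = "G"),
                   subjects = c("full", "edge", "low"))
  cr <- sample_call_rate(g)
  expect_equal(cr$call_rate, c(1, 0.97, 0.90))
  kept <- filter_samples(cr)
  expect_equal(kept$retained, "full")
  expect_true("edge" %in% kept$excluded$subject_id)
})

test_that("IBS distance has the required geometry and allele-flip invariance", {
  set.seed(5)
  calls <- matrix(rbinom(40 * 60, 2, 0.3), 40, 60)
  calls[1, ] <- calls[2, ]            # duplicate pair
  calls[3, ] <- 0L; calls[4, ] <- 2L  # maximally different pair
  g <- geno_matrix(calls, tibble::tibble(id = sprintf("v%03d", 1:60), chrom = "1",
                                         pos = 1:60, ref = "A", alt = "G"))
  d <- ibs_distance(g)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 40))
  expect_equal(d[1, 2], 0)
  expect_equal(d[3, 4], 1)
  # flipping a variant's allele labels (0 <-> 2) leaves IBS unchanged
  calls2 <- calls; calls2[, 7] <- 2L - calls2[, 7]
  g2 <- geno_matrix(calls2, variant_info(g))
  expect_equal(ibs_distance(g2), d)
  expect_error(ibs_distance(geno_subset(g, subjects = 1)), "2 samples")
})

test_that("inbreeding coefficient averages near zero for unrelated HWE samples", {
  g <- make_geno(120, 2000, maf = 0.3, seed = 8)
  f <- inbreeding_coeff(g)$f
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f)), 3 * se + 0.01)
})

test_that("classical MDS embeds exact 1-D configurations and separates populations", {
  x <- c(0, 3, 7)
  d <- abs(outer(x, x, "-"))
  emb <- mds_embed(d, k = 1)
  expect_equal(abs(outer(emb[, 1], emb[, 1], "-")), d, tolerance = 1e-9)

  # duplicate rows embed to identical coordinates
  d4 <- abs(outer(c(0, 3, 3, 7), c(0, 3, 3, 7), "-"))
  emb4 <- mds_embed(d4, k = 2)
  expect_equal(emb4[2, ], emb4[3, ], tolerance = 1e-9)

  set.seed(9)
  pop1 <- matrix(rbinom(40 * 300, 2, 0.15), 40, 300)
  pop2 <- matrix(rbinom(40 * 300, 2, 0.45), 40, 300)
  g <- geno_matrix(rbind(pop1, pop2),
                   tibble::tibble(id = sprintf("v%03d", 1:300), chrom = "1",
                                  pos = 1:300, ref = "A", alt = "G"))
  emb2 <- mds_embed(ibs_distance(g), k = 2)
  lab <- rep(c(0, 1), each = 40)
  expect_gt(abs(cor(emb2[, 1], lab)), 0.9)
  flags <- flag_outliers(emb2, mads = 6)
  expect_equal(length(flags), 80)
})

test_that("kinship filter drops the lower-call-rate member of close pairs", {
  calls <- matrix(rbinom(6 * 200, 2, 0.3), 6, 200)
  calls[2, ] <- calls[1, ]
  calls[2, 1:20] <- NA
  g <- geno_matrix(calls, tibble::tibble(id = sprintf("v%03d", 1:200), chrom = "1",
                                         pos = 1:200, ref = "A", alt = "G"))
  res <- kinship_filter(ibs_distance(g), sample_call_rate(g), max_dist = 0.05)
  expect_equal(res$excluded$subject_id, "S2")
  expect_equal(length(res$retained), 5)
})
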