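# Shared fixture builders (everything generated in code, no stored data).

# Independent binomial genotypes with simple metadata.
make_geno <- function(n, m, maf = 0.3, seed = 1, missing = 0) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 2, maf), n, m)
  if (missing > 0) calls[sample(length(calls), round(missing * length(calls)))] <- NA
  geno_matrix(calls,
              tibble::tibble(id = sprintf("v%03d", seq_len(m)), chrom = "13",
                             pos = 1000L * seq_len(m) + 47000000L,
                             ref = "A", alt = "G"))
}

# Minimal phenotype table with covariates and a continuous outcome.
make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    cohort = rep(c("A", "B"), length.out = n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(rnorm(n, 45, 12)),
    y = rnorm(n)
  )
}

# Independent enumeration oracle for the exact HWE test: direct closed-form
# conditional probability P(h) = n! 2^h na! nb! / (r! h! a! (2n)!) summed
# over configurations no more probable than the observed one.
hwe_oracle <- function(hr, het, ha) {
  n <- hr + het + ha
  na_ <- 2 * ha + het
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  prob <- vapply(hets, function(h) {
    a <- (na_ - h) / 2
    r <- n - h - a
    exp(lgamma(n + 1) - lgamma(r + 1) - lgamma(h + 1) - lgamma(a + 1) +
          h * log(2) + lgamma(na_ + 1) + lgamma(2 * n - na_ + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  obs <- prob[hets == het]
  sum(prob[prob <= obs + 1e-12])
}

# One-visit HRSD panel row from a vector of 21 item scores.
panel_row <- function(subject, week, items) {
  stopifnot(length(items) == 21)
  row <- tibble::tibble(subject_id = subject, week = as.integer(week))
  row[sprintf("item%02d", 1:21)] <- as.list(as.integer(items))
  row
}
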