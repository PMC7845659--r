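#' Minor-allele additive dosage for one variant
#'
#' Counts copies of the minor allele, with orientation computed on the
#' analysis sample: if the alternate allele frequency exceeds 0.5 the call
#' vector is flipped (2 - g).
#'
#' @param genotypes A [geno_matrix()].
#' @param variant Variant id.
#' @return Numeric vector of dosages with attributes `flipped` and
#'   `monomorphic`.
#' @export
additive_dosage <- function(genotypes, variant) {
  vi <- variant_info(genotypes)
  j <- match(variant, vi$id)
  if (is.na(j)) stop("variant not found: ", variant, call. = FALSE)
  g <- as.numeric(unclass(genotypes)[, j])
  af <- mean(g, na.rm = TRUE) / 2
  flipped <- !is.na(af) && af > 0.5
  if (flipped) g <- 2 - g
  structure(g, flipped = flipped,
            monomorphic = stats::var(g, na.rm = TRUE) %in% c(0, NA),
            names = rownames(genotypes))
}

# Map a phenotype vector to a 0/1 event indicator. Pipeline conventions:
# {1,2} codes take 2 as the event (the better outcome: remitted, or not
# stem-depressed), response/non-response takes response as the event, so
# OR > 1 always means better outcome for the minor allele.
as_event <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1, NA))) return(y)
  if (is.numeric(y) && all(y %in% c(1, 2, NA))) return(ifelse(is.na(y), NA, as.numeric(y == 2)))
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    lv <- sort(unique(stats::na.omit(y)))
    if (all(lv %in% c("response", "non-response"))) {
      return(ifelse(is.na(y), NA, as.numeric(y == "response")))
    }
    if (length(lv) == 2) return(ifelse(is.na(y), NA, as.numeric(y == lv[2])))
  }
  stop("cannot interpret phenotype as a binary event", call. = FALSE)
}

covariate_frame <- function(data, covariates) {
  if (!length(covariates)) return(data.frame(row.names = seq_len(nrow(data))))
  cf <- data[, covariates, drop = FALSE]
  as.data.frame(lapply(cf, function(x) if (is.character(x)) factor(x) else x))
}

#' Covariate-adjusted single-marker association test
#'
#' Additive (1-df) regression of a phenotype on a dosage vector with
#' covariate adjustment: least squares for continuous phenotypes, maximum-
#' likelihood logistic regression for binary ones, both tested by the Wald
#' statistic. Complete-case per variant.
#'
#' @param dosage Numeric dosage vector (e.g. [additive_dosage()]).
#' @param phenotype Outcome vector aligned with `dosage`; binary outcomes
#'   may be 0/1, codes \{1,2\} (2 = event) or "response"/"non-response".
#' @param covariates Data frame of covariates aligned with `dosage`
#'   (character columns become factors).
#' @param family `"linear"` or `"logistic"`.
#' @param min_n Minimum complete cases (default 10).
#' @return One-row tibble: beta, or (logistic only), se, statistic,
#'   p_value, n, status (`ok`, `monomorphic`, `not_converged`,
#'   `too_few`).
#' @export
single_marker_test <- function(dosage, phenotype, covariates = NULL,
                               family = c("linear", "logistic"), min_n = 10) {
  family <- match.arg(family)
  y <- if (family == "logistic") as_event(phenotype) else as.numeric(phenotype)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(dosage))
  df <- data.frame(.y = y, .g = as.numeric(dosage), covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  out <- tibble::tibble(beta = NA_real_, or = NA_real_, se = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        n = nrow(df), status = "ok")
  if (nrow(df) < min_n) { out$status <- "too_few"; return(out) }
  if (stats::var(df$.g) == 0) { out$status <- "monomorphic"; return(out) }
  rhs <- c(".g", setdiff(names(df), c(".y", ".g")))
  fml <- stats::reformulate(rhs, response = ".y")
  fit <- if (family == "linear") stats::lm(fml, data = df) else
    suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm[".g", 1]; se <- sm[".g", 2]
  converged <- if (family == "logistic") isTRUE(fit$converged) && se < 20 else TRUE
  if (!converged) { out$status <- "not_converged"; return(out) }
  stat <- beta / se
  p <- if (family == "linear") {
    2 * stats::pt(-abs(stat), stats::df.residual(fit))
  } else 2 * stats::pnorm(-abs(stat))
  out$beta <- beta; out$se <- se; out$statistic <- stat; out$p_value <- p
  if (family == "logistic") out$or <- exp(beta)
  out
}

#' Association scan over all variants
#'
#' Runs [single_marker_test()] for every variant against an outcome column
#' of a phenotype table, aligned by subject id. Results are ordered by
#' genomic position.
#'
#' @param genotypes A [geno_matrix()].
#' @param data Phenotype tibble containing `subject_id`, the outcome and
#'   the covariates.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (default age + sex).
#' @param family `"linear"` or `"logistic"`.
#' @return Tibble with one row per variant: id, chrom, pos, maf, family,
#'   beta, or, se, statistic, p_value, n, status.
#' @export
scan_markers <- function(genotypes, data, outcome,
                         covariates = c("age", "sex"),
                         family = c("linear", "logistic")) {
  family <- match.arg(family)
  idx <- match(rownames(genotypes), data$subject_id)
  if (all(is.na(idx))) stop("no genotype subjects found in phenotype table", call. = FALSE)
  y <- data[[outcome]][idx]
  cf <- covariate_frame(data, covariates)[idx, , drop = FALSE]
  vi <- variant_info(genotypes)
  res <- purrr::map_dfr(vi$id, function(v) {
    g <- additive_dosage(genotypes, v)
    single_marker_test(g, y, cf, family = family)
  })
  vi %>%
    dplyr::select("id", "chrom", "pos") %>%
    dplyr::mutate(maf = variant_stats(genotypes)$maf, family = family) %>%
    dplyr::bind_cols(res) %>%
    dplyr::arrange(.data$pos)
}

#' Case-control association scan
#'
#' Merges case and control genotype panels (allele-aligned via
#' [merge_cohorts()]) and runs a logistic scan of case status on dosage
#' plus covariates.
#'
#' @param case_geno,control_geno [geno_matrix()] objects.
#' @param case_data,control_data Optional covariate tibbles with
#'   `subject_id` (required when `covariates` is non-empty).
#' @param covariates Covariate column names (default none).
#' @return Tibble as [scan_markers()].
#' @export
case_control_scan <- function(case_geno, control_geno,
                              case_data = NULL, control_data = NULL,
                              covariates = character()) {
  if (is.null(control_geno) || nrow(control_geno) == 0) {
    stop("control panel is empty; case-control scan needs both groups", call. = FALSE)
  }
  if (nrow(case_geno) == 0) stop("case panel is empty", call. = FALSE)
  merged <- merge_cohorts(case_geno, control_geno)
  status <- tibble::tibble(
    subject_id = rownames(merged$genotypes),
    status = as.numeric(rownames(merged$genotypes) %in% rownames(case_geno))
  )
  if (length(covariates)) {
    covs <- dplyr::bind_rows(case_data, control_data)
    status <- status %>% dplyr::left_join(covs, by = "subject_id")
  }
  scan_markers(merged$genotypes, status, "status",
               covariates = covariates, family = "logistic")
}

#' Two-group difference test
#'
#' Student's two-sample t-test (pooled variance) for continuous variables;
#' Pearson chi-square without continuity correction for categorical ones.
#' A variable with more than `cat_max` distinct values is treated as
#' continuous.
#'
#' @param data Tibble.
#' @param variable Column to test.
#' @param group Grouping column (two groups).
#' @param cat_max Maximum distinct values for categorical treatment
#'   (default 5).
#' @return One-row tibble: method, statistic, p_value.
#' @export
difference_test <- function(data, variable, group, cat_max = 5) {
  x <- data[[variable]]; g <- data[[group]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- factor(g[keep])
  if (nlevels(g) != 2) stop("grouping variable must have exactly two groups", call. = FALSE)
  continuous <- is.numeric(x) && length(unique(x)) > cat_max
  if (continuous) {
    if (min(table(g)) < 2) stop("each group needs at least 2 observations", call. = FALSE)
    tt <- stats::t.test(x ~ g, var.equal = TRUE)
    tibble::tibble(method = "t", statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table(g, x), correct = FALSE))
    tibble::tibble(method = "chisq", statistic = unname(ct$statistic), p_value = ct$p.value)
  }
}

# ---- fast marker-p engine (used by the gene-based permutation test) ----
#
# Linear family: partial-correlation t test of each dosage column against
# the covariate-residualized phenotype -- algebraically identical to the
# Wald t from lm(y ~ covariates + g). Logistic family: efficient score
# test against the null model y ~ covariates (fitted once; its weights are
# unchanged by genotype permutation).

marker_engine <- function(y, X, family) {
  if (family == "linear") {
    qrX <- qr(X)
    yres <- qr.resid(qrX, y)
    yss <- sum(yres^2)
    df <- length(y) - ncol(X) - 1
    list(
      pvals = function(G) {
        Gres <- qr.resid(qrX, G)
        gss <- colSums(Gres^2)
        r2 <- (crossprod(Gres, yres)[, 1])^2 / (gss * yss)
        r2[gss <= 0] <- NA_real_
        tstat2 <- r2 * df / (1 - r2)
        stats::pf(tstat2, 1, df, lower.tail = FALSE)
      })
  } else {
    fit0 <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- fit0$fitted.values
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    resid0 <- y - mu
    list(
      pvals = function(G) {
        B <- solve(XtWX, crossprod(X * w, G))
        Gadj <- G - X %*% B
        U <- crossprod(G, resid0)[, 1]
        V <- colSums(w * G * Gadj)
        z2 <- U^2 / V
        z2[V <= 0] <- NA_real_
        stats::pchisq(z2, 1, lower.tail = FALSE)
      })
  }
}
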