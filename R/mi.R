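#' Multiple imputation of missing phenotype values
#'
#' Chained-equation stochastic regression imputation. Each incomplete
#' weekly measure is regressed (normal linear model) on the covariates and
#' the other weekly measures; missing cells are filled by the regression
#' prediction plus a residual draw from the fitted residual distribution,
#' so subjects with identical predictor values receive different imputed
#' values. The chained pass over all incomplete variables is repeated
#' `cycles` times per completed dataset, and the whole procedure `m` times.
#' Phenotype codes (remitted / response / stem) are re-derived from the
#' imputed continuous measures so the coding rules stay single-sourced.
#'
#' @param table Phenotype tibble from [build_phenotypes()], possibly with
#'   `NA` weekly totals / item-1 scores.
#' @param predictors Fully observed predictor columns (sex is coded
#'   numerically internally).
#' @param m Number of completed datasets (default 30).
#' @param cycles Chained passes per dataset (default 4).
#' @param seed Integer seed.
#' @return An object of class `imputed_stack`: list with `tables` (list of
#'   m completed tibbles), `m`, `cycles`, `seed`, `predictors`.
#' @export
impute_stack <- function(table, predictors = c("age", "sex", "baseline_total"),
                         m = 30, cycles = 4, seed = 1L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  targets_all <- c("week2_total", "week4_total", "week8_total", "item1_week4")
  targets <- targets_all[vapply(targets_all, function(v) anyNA(table[[v]]), logical(1))]
  for (v in targets) {
    if (all(is.na(table[[v]]))) stop("column ", v, " is entirely missing", call. = FALSE)
  }
  work0 <- table
  work0$.sex_num <- as.numeric(factor(table$sex, levels = c("female", "male")))
  preds <- sub("^sex$", ".sex_num", predictors)
  if (!length(targets)) {
    return(structure(list(tables = rep(list(table), m), m = m, cycles = cycles,
                          seed = as.integer(seed), predictors = predictors),
                     class = "imputed_stack"))
  }
  obs_idx <- lapply(targets, function(v) which(!is.na(table[[v]])))
  names(obs_idx) <- targets

  one_imputation <- function(i) {
    set.seed(derive_seed(seed, paste0("impute", i)))
    work <- work0
    for (v in targets) {
      miss <- which(is.na(work[[v]]))
      work[[v]][miss] <- sample(work[[v]][obs_idx[[v]]], length(miss), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (v in targets) {
        rhs <- c(preds, setdiff(targets, v))
        fml <- stats::reformulate(rhs, response = v)
        fit <- stats::lm(fml, data = work[obs_idx[[v]], , drop = FALSE])
        miss <- setdiff(seq_len(nrow(work)), obs_idx[[v]])
        mu <- stats::predict(fit, newdata = work[miss, , drop = FALSE])
        sigma <- summary(fit)$sigma
        if (!is.finite(sigma)) sigma <- 0
        work[[v]][miss] <- mu + stats::rnorm(length(miss), 0, sigma)
      }
    }
    work$item1_week4 <- pmin(pmax(work$item1_week4, 0), 4)
    resp <- derive_response(work$baseline_total, work$week4_total)
    work %>%
      dplyr::mutate(remitted_code = derive_remitted(.data$week8_total),
                    pct_change = resp$pct_change,
                    response_code = resp$response_code,
                    stem_code = derive_stem(.data$item1_week4)) %>%
      dplyr::select(-".sex_num")
  }
  tables <- lapply(seq_len(m), one_imputation)
  structure(list(tables = tables, m = m, cycles = cycles, seed = as.integer(seed),
                 predictors = predictors),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("<imputed_stack> m =", x$m, "completed datasets,", x$cycles, "cycles, seed", x$seed, "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate `Q = mean(estimates)`, within-imputation variance
#' `W = mean(variances)`, between-imputation variance `B = var(estimates)`
#' (defined as 0 for m = 1), total variance `T = W + (1 + 1/m) B`, degrees
#' of freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2` (Barnard-Rubin adjusted
#' when `dfcom` is supplied), and a two-sided p-value from the t reference.
#'
#' @param estimates,variances Equal-length numeric vectors (one entry per
#'   completed dataset); variances must be non-negative.
#' @param dfcom Optional complete-data residual degrees of freedom for the
#'   small-sample adjustment.
#' @return An object of class `pooled_estimate`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = NULL) {
  m <- length(estimates)
  if (m == 0) stop("no estimates to pool", call. = FALSE)
  if (length(variances) != m) stop("estimates and variances differ in length", call. = FALSE)
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  tvar <- wbar + (1 + 1 / m) * b
  if (b > 0) {
    rm_ <- (1 + 1 / m) * b / wbar
    df_old <- (m - 1) * (1 + 1 / rm_)^2
    if (!is.null(dfcom)) {
      lambda <- (1 + 1 / m) * b / tvar
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- Inf
  }
  se <- sqrt(tvar)
  stat <- if (se > 0) qbar / se else NA_real_
  p <- if (is.na(stat)) NA_real_ else if (is.finite(df)) {
    2 * stats::pt(-abs(stat), df)
  } else 2 * stats::pnorm(-abs(stat))
  structure(list(estimate = qbar, within = wbar, between = b, total = tvar,
                 m = m, df = df, statistic = stat, p_value = p),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> Q = %.4g (se %.4g), m = %d, df = %.3g, p = %.3g\n",
              x$estimate, sqrt(x$total), x$m, x$df, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pooled_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = sqrt(x$total),
                 statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' @exportS3Method generics::glance
glance.pooled_estimate <- function(x, ...) {
  tibble::tibble(m = x$m, within = x$within, between = x$between, total = x$total)
}

#' Fit a model on every completed dataset and pool the coefficients
#'
#' Convenience wrapper: fits `lm()` (gaussian) or `glm()` on each table of
#' an [impute_stack()] result and pools each coefficient by [pool_rubin()].
#'
#' @param stack An `imputed_stack`.
#' @param formula Model formula.
#' @param family A glm family, or `stats::gaussian()` for least squares.
#' @return Tibble with one row per model term: estimate, std.error,
#'   statistic, df, p.value.
#' @export
pool_fit <- function(stack, formula, family = stats::gaussian()) {
  stopifnot(inherits(stack, "imputed_stack"))
  fits <- lapply(stack$tables, function(tab) {
    if (identical(family$family, "gaussian")) stats::lm(formula, data = tab)
    else stats::glm(formula, data = tab, family = family)
  })
  terms <- names(stats::coef(fits[[1]]))
  dfcom <- stats::df.residual(fits[[1]])
  purrr::map_dfr(terms, function(tm) {
    est <- vapply(fits, function(f) stats::coef(f)[[tm]], numeric(1))
    va <- vapply(fits, function(f) stats::vcov(f)[tm, tm], numeric(1))
    tidy(pool_rubin(est, va, dfcom = dfcom)) %>% dplyr::mutate(term = tm, .before = 1)
  })
}
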