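#' HRSD-21 total score at a visit
#'
#' @param panel HRSD panel tibble (subject_id, week, item01..item21).
#' @param subject Subject id.
#' @param week Visit week, one of 0, 2, 4, 8.
#' @return Integer total of the 21 items, or `NA` if the visit is missing.
#' @export
hrsd_total <- function(panel, subject, week) {
  if (!week %in% c(0, 2, 4, 8)) stop("week must be one of 0, 2, 4, 8", call. = FALSE)
  row <- panel[panel$subject_id == subject & panel$week == week, ]
  if (!nrow(row)) stop("unknown subject/week: ", subject, " week ", week, call. = FALSE)
  items <- as.numeric(row[1, sprintf("item%02d", 1:21)])
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

#' Remission code from the week-8 HRSD total
#'
#' Coded 1 if the total exceeds 7 and 2 (remitted) otherwise; a total of
#' exactly 7 is remitted.
#'
#' @param week8_total Numeric vector of week-8 totals (`NA` passes through).
#' @return Integer codes in \{1, 2\}.
#' @export
derive_remitted <- function(week8_total) {
  ifelse(is.na(week8_total), NA_integer_, ifelse(week8_total > 7, 1L, 2L))
}

#' Response status from the week-4 percentage change
#'
#' `pct_change = (week4 - baseline) / baseline` (negative = improvement).
#' A reduction of at least 50% (pct_change <= -0.5) is a response; exactly
#' 50% counts as response.
#'
#' @param baseline_total,week4_total Numeric vectors; baseline must be > 0.
#' @return Tibble with `pct_change` and `response_code`
#'   ("response"/"non-response", `NA` where week 4 is missing).
#' @export
derive_response <- function(baseline_total, week4_total) {
  if (any(!is.na(baseline_total) & baseline_total <= 0)) {
    stop("baseline total must be positive to define percentage change", call. = FALSE)
  }
  pct_change <- (week4_total - baseline_total) / baseline_total
  tibble::tibble(
    pct_change = pct_change,
    response_code = ifelse(is.na(pct_change), NA_character_,
                           ifelse(pct_change <= -0.5, "response", "non-response"))
  )
}

#' Stem-depressed code from HRSD item 1 at week 4
#'
#' Item 1 ("depressed mood") of 3 or 4 — moderately severe or severe — is
#' coded 1; lower scores are coded 2.
#'
#' @param item1_week4 Integer vector of item-1 scores (0-4, `NA` allowed).
#' @return Integer codes in \{1, 2\}.
#' @export
derive_stem <- function(item1_week4) {
  if (any(!is.na(item1_week4) & (item1_week4 < 0 | item1_week4 > 4))) {
    stop("item 1 scores must lie in 0..4", call. = FALSE)
  }
  ifelse(is.na(item1_week4), NA_integer_, ifelse(item1_week4 >= 3, 1L, 2L))
}

#' Derive all four treatment-response phenotypes
#'
#' One row per subject: remission at week 8, binary response and continuous
#' percent change at week 4, stem-depressed at week 4, the weekly totals
#' they came from, and covariates. Phenotypes whose defining visit is
#' missing are `NA`.
#'
#' @param panel HRSD panel tibble.
#' @param subjects Subject covariate tibble (subject_id, cohort, sex, age).
#' @return A phenotype tibble.
#' @export
build_phenotypes <- function(panel, subjects) {
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject id", call. = FALSE)
  item_cols <- sprintf("item%02d", 1:21)
  totals <- panel %>%
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(item_cols)))) %>%
    dplyr::select("subject_id", "week", "total", item1 = "item01") %>%
    tidyr::pivot_wider(names_from = "week", values_from = c("total", "item1"))
  need <- c("total_0", "total_2", "total_4", "total_8", "item1_4")
  for (nm in setdiff(need, names(totals))) totals[[nm]] <- NA_real_
  out <- subjects %>%
    dplyr::inner_join(totals, by = "subject_id") %>%
    dplyr::rename(baseline_total = "total_0", week2_total = "total_2",
                  week4_total = "total_4", week8_total = "total_8",
                  item1_week4 = "item1_4") %>%
    dplyr::select(-dplyr::starts_with("item1_"), "item1_week4")
  resp <- derive_response(out$baseline_total, out$week4_total)
  out %>%
    dplyr::mutate(
      remitted_code = derive_remitted(.data$week8_total),
      pct_change = resp$pct_change,
      response_code = resp$response_code,
      stem_code = derive_stem(.data$item1_week4)
    ) %>%
    dplyr::select("subject_id", "cohort", "sex", "age",
                  dplyr::any_of("drug"),
                  "baseline_total", "week2_total", "week4_total", "week8_total",
                  "item1_week4", "remitted_code", "pct_change",
                  "response_code", "stem_code")
}

#' Summaries of response and remission rates
#'
#' Reports each rate with its numerator and denominator, remission by week
#' (total <= 7 at weeks 2/4/8), the week-4 response rate, the
#' stem-depressed severity split, and sex-difference tests (two-sample t
#' for continuous measures, chi-square for categorical codes).
#'
#' @param table Phenotype tibble from [build_phenotypes()].
#' @return A list with tibbles `rates` (measure, numerator, denominator,
#'   percent) and `sex_tests` (measure, method, statistic, p_value).
#' @export
summarize_rates <- function(table) {
  if (!nrow(table)) stop("empty phenotype table", call. = FALSE)
  rate_row <- function(measure, num, den) {
    tibble::tibble(measure = measure, numerator = num, denominator = den,
                   percent = pct(num, den))
  }
  rem_week <- function(col, wk) {
    obs <- table[[col]][!is.na(table[[col]])]
    rate_row(paste0("remission_week", wk), sum(obs <= 7), length(obs))
  }
  resp_obs <- table$response_code[!is.na(table$response_code)]
  stem_obs <- table$stem_code[!is.na(table$stem_code)]
  rates <- dplyr::bind_rows(
    rem_week("week2_total", 2), rem_week("week4_total", 4), rem_week("week8_total", 8),
    rate_row("response_week4", sum(resp_obs == "response"), length(resp_obs)),
    rate_row("stem_depressed", sum(stem_obs == 1), length(stem_obs)),
    rate_row("stem_not_depressed", sum(stem_obs == 2), length(stem_obs)),
    rate_row("female", sum(table$sex == "female"), nrow(table))
  )
  sex_tests <- dplyr::bind_rows(
    difference_test(table, "week8_total", "sex") %>% dplyr::mutate(measure = "week8_total"),
    difference_test(table, "pct_change", "sex") %>% dplyr::mutate(measure = "pct_change"),
    difference_test(table, "stem_code", "sex") %>% dplyr::mutate(measure = "stem_code")
  ) %>% dplyr::select("measure", "method", "statistic", "p_value")
  list(rates = rates, sex_tests = sex_tests)
}
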