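#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @import dplyr
NULL

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Derive a child seed from a master seed and a stage label, staying within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Percentage with the numerator/denominator kept alongside.
pct <- function(n, total) 100 * n / total

fmt_n_pct <- function(n, total, digits = 2) {
  sprintf("%d (%.*f)", n, digits, pct(n, total))
}

fmt_mean_sd <- function(x, digits = 2) {
  sprintf("%.*f (%.*f)", digits, mean(x, na.rm = TRUE), digits, stats::sd(x, na.rm = TRUE))
}

assert_prob <- function(x, name = deparse(substitute(x))) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
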