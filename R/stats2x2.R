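#' 2x2 association statistics
#'
#' Every comparison in the pipeline reduces to a 2x2 table of a category
#' against all remaining categories in two groups:
#' \preformatted{
#'              category   rest
#'   cases          a        b
#'   controls       c        d
#' }
#'
#' `cross_product_or()` is the cross-product estimator (a*d)/(b*c);
#' `conditional_or()` the conditional maximum-likelihood estimator of the
#' hypergeometric model (the estimate reported by [stats::fisher.test()]),
#' which some small-count published tables used instead.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return `cross_product_or()`/`conditional_or()`: a number (`NA` when the
#'   estimator is undefined, i.e. `b*c == 0` for the cross-product).
#' @export
cross_product_or <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  if (b * c == 0) return(NA_real_)
  (a * d) / (b * c)
}

#' @rdname cross_product_or
#' @export
conditional_or <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  unname(stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$estimate)
}

.check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  invisible(cells)
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-scale normal approximation:
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Undefined (returns
#' `NA` bounds) when any cell is zero.
#'
#' @inheritParams cross_product_or
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  .check_cells(a, b, c, d)
  if (any(c(a, b, c, d) == 0)) return(c(low = NA_real_, high = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(low = exp(lo - z * se), high = exp(lo + z * se))
}

#' Pearson chi-square p-value (1 df, no continuity correction)
#'
#' Two-sided p from `N*(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. No Yates
#' correction is applied. Requires all four margins positive.
#'
#' @inheritParams cross_product_or
#' @return two-sided p-value.
#' @export
pearson_chi2_p <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  if (any(c(a + b, c + d, a + c, b + d) == 0)) {
    stop("chi-square undefined: zero margin", call. = FALSE)
  }
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}

#' Fisher exact two-sided p-value
#'
#' Two-sided p as the total hypergeometric probability of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (the convention of [stats::fisher.test()]).
#'
#' @inheritParams cross_product_or
#' @return two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
}

#' Expected cell counts of a 2x2 table
#' @inheritParams cross_product_or
#' @return 2x2 matrix of expected counts under independence.
#' @export
expected_cells <- function(a, b, c, d) {
  .check_cells(a, b, c, d)
  n <- a + b + c + d
  outer(c(a + b, c + d), c(a + c, b + d)) / n
}

#' Choose the test for a 2x2 table
#'
#' Default rule (`"expected5"`): Fisher's exact test when any expected cell
#' count is below 5 (or any margin is zero), Pearson chi-square otherwise.
#' `"chi2"` and `"fisher"` force the respective test.
#'
#' @inheritParams cross_product_or
#' @param rule selection rule.
#' @return `"chi2"` or `"fisher"`.
#' @export
choose_test <- function(a, b, c, d, rule = c("expected5", "chi2", "fisher")) {
  rule <- match.arg(rule)
  if (rule != "expected5") return(rule)
  if (any(c(a + b, c + d, a + c, b + d) == 0)) return("fisher")
  if (any(expected_cells(a, b, c, d) < 5)) "fisher" else "chi2"
}

#' Full association result for one 2x2 table
#'
#' @inheritParams cross_product_or
#' @param estimator `"cross"` (cross-product, default) or `"conditional"`
#'   (conditional MLE; its CI is then the exact conditional interval from
#'   [stats::fisher.test()]).
#' @param test_rule passed to [choose_test()].
#' @param level confidence level.
#' @return one-row data.frame: `a,b,c,d`, `or`, `ci_low`, `ci_high`, `p`,
#'   `test_used`.
#' @export
assoc_2x2 <- function(a, b, c, d, estimator = c("cross", "conditional"),
                      test_rule = "expected5", level = 0.95) {
  estimator <- match.arg(estimator)
  test <- choose_test(a, b, c, d, test_rule)
  p <- if (test == "chi2") pearson_chi2_p(a, b, c, d) else fisher_exact_p(a, b, c, d)
  if (estimator == "cross") {
    or <- cross_product_or(a, b, c, d)
    ci <- woolf_ci(a, b, c, d, level)
  } else {
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                             conf.level = level)
    or <- unname(ft$estimate)
    ci <- ft$conf.int
  }
  data.frame(a = a, b = b, c = c, d = d, or = unname(or),
             ci_low = unname(ci[1]), ci_high = unname(ci[2]), p = p,
             test_used = test, stringsAsFactors = FALSE)
}
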