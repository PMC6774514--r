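#' Relative predispositional effects (RPE) by sequential elimination
#'
#' Each round tests every remaining category against the rest of its group
#' totals (test per [choose_test()]). The category with the smallest
#' p-value is the round's candidate; it is excluded -- its counts removed
#' from both group totals -- when its p-value is below `alpha` and its case
#' count is at least `min_case_count` (categories carried by at most one
#' case are never considered significant). The procedure repeats on the
#' reduced totals until no further category qualifies. The trace records
#' every round's complete per-category p-values and test choices, which is
#' the multi-column p structure of the published tables.
#'
#' Ties on the minimal p are broken by the larger absolute deviation of the
#' observed case count from its expected value, then by label order, so the
#' trace is deterministic.
#'
#' @param case_counts,control_counts named count vectors over the same
#'   category universe (missing labels are zero-filled).
#' @param alpha significance threshold for exclusion (default 0.05).
#' @param min_case_count minimal case count for exclusion (default 2).
#' @param test_rule passed to [choose_test()].
#' @param background labels that contribute to the totals but are never
#'   tested or excluded (e.g. the pooled remainder of a published table,
#'   see [freq_from_counts()]).
#' @return object of class `rpe_trace`: list with `rounds` (each holding
#'   `round_index`, `p`, `test`, `case_total`, `control_total`,
#'   `excluded`), `significant` (excluded categories in round order),
#'   `alpha`, `min_case_count`.
#' @export
run_rpe <- function(case_counts, control_counts, alpha = 0.05,
                    min_case_count = 2, test_rule = "expected5",
                    background = NULL) {
  labels <- sort(union(names(case_counts), names(control_counts)))
  if (length(labels) == 0) stop("empty RPE input", call. = FALSE)
  ca <- stats::setNames(rep(0, length(labels)), labels)
  co <- ca
  ca[names(case_counts)] <- case_counts
  co[names(control_counts)] <- control_counts
  case_total <- sum(ca)
  control_total <- sum(co)
  if (case_total <= 0 || control_total <= 0) {
    stop("RPE requires positive group totals", call. = FALSE)
  }

  remaining <- labels
  rounds <- list()
  significant <- character()
  repeat {
    eligible <- setdiff(remaining, background)
    if (length(eligible) == 0) break
    p <- stats::setNames(rep(NA_real_, length(eligible)), eligible)
    test <- stats::setNames(rep(NA_character_, length(eligible)), eligible)
    dev <- p
    for (l in eligible) {
      a <- ca[[l]]; b <- case_total - a
      c_ <- co[[l]]; d <- control_total - c_
      n <- a + b + c_ + d
      if (a + c_ == 0 || b + d == 0) next  # degenerate: category is all or nothing
      test[[l]] <- choose_test(a, b, c_, d, test_rule)
      p[[l]] <- if (test[[l]] == "chi2") pearson_chi2_p(a, b, c_, d)
                else fisher_exact_p(a, b, c_, d)
      dev[[l]] <- abs(a - (a + b) * (a + c_) / n)
    }
    if (all(is.na(p))) break
    ord <- order(p, -dev, eligible, na.last = TRUE)
    cand <- eligible[ord[1]]
    exclude <- !is.na(p[[cand]]) && p[[cand]] < alpha && ca[[cand]] >= min_case_count
    rounds[[length(rounds) + 1]] <- list(
      round_index = length(rounds) + 1L,
      p = p, test = test,
      case_total = case_total, control_total = control_total,
      excluded = if (exclude) cand else NA_character_
    )
    if (!exclude) break
    significant <- c(significant, cand)
    case_total <- case_total - ca[[cand]]
    control_total <- control_total - co[[cand]]
    remaining <- setdiff(remaining, cand)
    if (case_total <= 0 || control_total <= 0) break
  }

  structure(list(rounds = rounds, significant = significant, alpha = alpha,
                 min_case_count = min_case_count, background = background,
                 case_counts = ca, control_counts = co),
            class = "rpe_trace")
}

#' @export
print.rpe_trace <- function(x, ...) {
  cat("<rpe_trace> ", length(x$rounds), " round(s); excluded: ",
      if (length(x$significant)) paste(x$significant, collapse = " > ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Tabulate an RPE trace
#'
#' One row per tested category, one p column per round; cells are blank
#' (`NA`) from the round after a category's exclusion onward, mirroring the
#' staggered p columns of the published tables.
#'
#' @param x an `rpe_trace`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `category`, `case_n`, `control_n`,
#'   `excluded_round`, `p_round1`, `p_round2`, ...
#' @export
as.data.frame.rpe_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  cats <- setdiff(names(x$case_counts), x$background)
  out <- data.frame(category = cats,
                    case_n = as.numeric(x$case_counts[cats]),
                    control_n = as.numeric(x$control_counts[cats]),
                    excluded_round = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in x$rounds) {
    col <- paste0("p_round", r$round_index)
    out[[col]] <- NA_real_
    idx <- match(names(r$p), out$category)
    out[[col]][idx] <- as.numeric(r$p)
    if (!is.na(r$excluded)) {
      out$excluded_round[match(r$excluded, out$category)] <- r$round_index
    }
  }
  out
}
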