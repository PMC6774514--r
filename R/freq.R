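#' Build a frequency table of categories per group
#'
#' Counting units:
#' \describe{
#'   \item{`haplotype_slots`}{each subject contributes one count per
#'     chromosome (two rows per subject in `x`); denominators are total
#'     slots per group, i.e. 2 x subjects typed.}
#'   \item{`carriers`}{each subject counts once per category carried
#'     (at least one copy); denominators are subjects per group.}
#'   \item{`subjects`}{one row per subject (e.g. genotype categories);
#'     denominators are subjects per group.}
#' }
#'
#' @param x data.frame with columns `subject_id`, `group`, `category`
#'   (one row per allele/haplotype slot, or one per subject for
#'   `unit = "subjects"`). Rows with `NA` category are dropped (and for
#'   slot counting do not enter the denominator).
#' @param unit counting unit.
#' @return object of class `hla_freq`: list with `counts` (category x group
#'   matrix), `denom` (named vector), `pct`, `unit`.
#' @export
build_frequency_table <- function(x, unit = c("haplotype_slots", "carriers",
                                              "subjects")) {
  unit <- match.arg(unit)
  stopifnot(all(c("subject_id", "group", "category") %in% names(x)))
  groups <- sort(unique(x$group))
  if (unit == "carriers") {
    denom_src <- unique(x[c("subject_id", "group")])
    x <- unique(x[!is.na(x$category), c("subject_id", "group", "category")])
    denom <- table(factor(denom_src$group, levels = groups))
  } else {
    x <- x[!is.na(x$category), ]
    denom <- table(factor(x$group, levels = groups))
  }
  counts <- table(factor(x$category), factor(x$group, levels = groups))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  denom <- stats::setNames(as.integer(denom), groups)
  new_freq(counts, denom, unit)
}

new_freq <- function(counts, denom, unit) {
  stopifnot(identical(colnames(counts), names(denom)))
  # carrier counts need not sum to the denominator (a subject can carry two
  # categories), but no single category can exceed it
  bad <- if (unit == "carriers") any(counts > matrix(denom, nrow(counts),
                                                    ncol(counts), byrow = TRUE))
         else any(colSums(counts) > denom)
  if (bad) stop("category counts exceed group denominator", call. = FALSE)
  pct <- sweep(counts, 2, denom, "/") * 100
  structure(list(counts = counts, denom = denom, pct = pct, unit = unit),
            class = "hla_freq")
}

#' @export
print.hla_freq <- function(x, ...) {
  cat("<hla_freq> unit=", x$unit, ", ", nrow(x$counts), " categories; denominators: ",
      paste(names(x$denom), x$denom, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Frequency table from published category counts
#'
#' Fixture-driven mode: published tables give counts for selected
#' categories plus group totals. The unlisted remainder is pooled into a
#' single category (default label `"other"`) so that denominators are
#' conserved; the pooled remainder is an artifact of publication, not a
#' real category, and should be passed as `background` to [run_rpe()] and
#' excluded from per-category association output.
#'
#' @param counts data.frame with columns `category`, `case_n`, `control_n`.
#' @param case_total,control_total group denominators.
#' @param case_label,control_label group names (default `"NT1"`, `"GP"`).
#' @param other_label label of the pooled remainder (set `NULL` to require
#'   counts that already sum to the totals).
#' @param unit stored counting unit tag.
#' @return an `hla_freq`.
#' @export
freq_from_counts <- function(counts, case_total, control_total,
                             case_label = "NT1", control_label = "GP",
                             other_label = "other",
                             unit = "haplotype_slots") {
  stopifnot(all(c("category", "case_n", "control_n") %in% names(counts)))
  if (anyDuplicated(counts$category)) stop("duplicate category", call. = FALSE)
  ca <- sum(counts$case_n)
  co <- sum(counts$control_n)
  if (ca > case_total || co > control_total) {
    stop("counts exceed declared group totals", call. = FALSE)
  }
  cats <- counts$category
  m <- cbind(counts$case_n, counts$control_n)
  if (!is.null(other_label) && (case_total - ca > 0 || control_total - co > 0)) {
    if (other_label %in% cats) stop("remainder label collides with a category",
                                    call. = FALSE)
    cats <- c(cats, other_label)
    m <- rbind(m, c(case_total - ca, control_total - co))
  }
  counts_m <- matrix(as.integer(m), ncol = 2,
                     dimnames = list(cats, c(case_label, control_label)))
  # keep group columns in name order for determinism
  ord <- order(colnames(counts_m))
  counts_m <- counts_m[, ord, drop = FALSE]
  denom <- stats::setNames(c(case_total, control_total),
                           c(case_label, control_label))[colnames(counts_m)]
  new_freq(counts_m, denom, unit)
}

#' 2x2 table of one category against the rest
#'
#' @param freq an `hla_freq`.
#' @param category row label.
#' @param case_group,control_group column labels.
#' @return named numeric `c(a, b, c, d)`.
#' @export
category_vs_rest <- function(freq, category, case_group, control_group) {
  stopifnot(inherits(freq, "hla_freq"))
  if (!category %in% rownames(freq$counts)) {
    stop("category '", category, "' absent from the table", call. = FALSE)
  }
  a <- freq$counts[category, case_group]
  c_ <- freq$counts[category, control_group]
  c(a = a, b = freq$denom[[case_group]] - a,
    c = c_, d = freq$denom[[control_group]] - c_)
}

#' Association results for every category of a frequency table
#'
#' @param freq an `hla_freq`.
#' @param case_group,control_group column labels.
#' @param categories categories to test (default all except `exclude`).
#' @param exclude labels to drop (e.g. a pooled remainder).
#' @param estimator,test_rule,level passed to [assoc_2x2()].
#' @return data.frame with one row per category: counts, percentages, OR,
#'   Woolf CI, p, test used, plus the table cells for auditability.
#' @export
associate_all <- function(freq, case_group, control_group,
                          categories = NULL, exclude = NULL,
                          estimator = "cross", test_rule = "expected5",
                          level = 0.95) {
  stopifnot(inherits(freq, "hla_freq"))
  if (is.null(categories)) categories <- rownames(freq$counts)
  categories <- setdiff(categories, exclude)
  rows <- lapply(categories, function(cat) {
    t <- category_vs_rest(freq, cat, case_group, control_group)
    res <- assoc_2x2(t[["a"]], t[["b"]], t[["c"]], t[["d"]],
                     estimator = estimator, test_rule = test_rule,
                     level = level)
    cbind(data.frame(category = cat,
                     case_n = t[["a"]],
                     case_pct = 100 * t[["a"]] / freq$denom[[case_group]],
                     control_n = t[["c"]],
                     control_pct = 100 * t[["c"]] / freq$denom[[control_group]],
                     stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition categories into common and rare
#'
#' A category is common when its frequency is at least `threshold` percent
#' in any group (inclusive boundary); the rest are rare. The partition is
#' exhaustive and disjoint.
#'
#' @param freq an `hla_freq`.
#' @param threshold percent (default 1).
#' @return list with character vectors `common` and `rare`.
#' @export
rare_partition <- function(freq, threshold = 1) {
  stopifnot(inherits(freq, "hla_freq"))
  if (nrow(freq$counts) == 0) return(list(common = character(), rare = character()))
  common <- apply(freq$pct >= threshold, 1, any)
  list(common = rownames(freq$counts)[common],
       rare = rownames(freq$counts)[!common])
}
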