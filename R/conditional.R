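#' Select carriers of the anchor haplotype in one group
#'
#' Partitions a group's phased subjects into carriers (at least one anchor
#' haplotype), homozygotes (two anchor copies) and heterozygotes, and
#' collects the non-anchor "second" haplotype of every heterozygote.
#' Matching is done at a configurable field resolution because the anchor
#' may be written at two- or three-field resolution. Unresolved subjects
#' are excluded and counted in `n_unresolved`.
#'
#' @param phased data.frame from [assemble_by_anchor()] or
#'   [phase_families()] with an added `group` column (see
#'   [run_pipeline()]), or any data.frame with `subject_id`, `group`,
#'   `hap1`, `hap2`, `provenance`.
#' @param anchor anchor haplotype label.
#' @param group group to select (e.g. `"NT1"`).
#' @param resolution field resolution for anchor matching (default 3).
#' @return object of class `carrier_set`: list with `group`, `carriers`,
#'   `homozygotes`, `heterozygotes` (subject ids), `second_haplotypes`
#'   (one label per heterozygote), `n_unresolved`.
#' @export
select_carriers <- function(phased, anchor, group, resolution = 3) {
  stopifnot(all(c("subject_id", "group", "hap1", "hap2") %in% names(phased)))
  x <- phased[phased$group == group, ]
  unres <- is.na(x$hap1) | is.na(x$hap2)
  if ("provenance" %in% names(x)) unres <- unres | x$provenance == "unresolved"
  n_unresolved <- sum(unres)
  x <- x[!unres, ]
  m1 <- hap_matches(x$hap1, anchor, resolution)
  m2 <- hap_matches(x$hap2, anchor, resolution)
  carriers <- x[m1 | m2, ]
  hom <- m1[m1 | m2] & m2[m1 | m2]
  second <- ifelse(hap_matches(carriers$hap1, anchor, resolution),
                   carriers$hap2, carriers$hap1)
  structure(list(group = group,
                 carriers = carriers$subject_id,
                 homozygotes = carriers$subject_id[hom],
                 heterozygotes = carriers$subject_id[!hom],
                 second_haplotypes = second[!hom],
                 n_unresolved = n_unresolved),
            class = "carrier_set")
}

#' @export
print.carrier_set <- function(x, ...) {
  cat("<carrier_set> ", x$group, ": ", length(x$carriers), " carriers (",
      length(x$homozygotes), " homozygous, ", length(x$heterozygotes),
      " heterozygous); ", x$n_unresolved, " unresolved excluded\n", sep = "")
  invisible(x)
}

#' Second-haplotype association among anchor heterozygotes
#'
#' For each haplotype observed opposite the anchor, a 2x2 table of carriers
#' with that second haplotype versus carriers without it, cases versus
#' controls. The default denominator is the heterozygous carriers (each
#' contributes exactly one second haplotype); carrier totals are reported
#' alongside because published percentages are ambiguous about the
#' denominator.
#'
#' @param cases,controls [select_carriers()] results.
#' @param denominator `"heterozygotes"` (default) or `"carriers"`.
#' @param estimator,test_rule,level passed to [assoc_2x2()].
#' @return data.frame, one row per second haplotype present in either
#'   group, with counts, percentages under the chosen denominator, OR, CI,
#'   p, test used, and the candidate denominators
#'   (`case_het_total`, `case_carrier_total`, ...).
#' @export
second_haplotype_association <- function(cases, controls,
                                         denominator = c("heterozygotes",
                                                         "carriers"),
                                         estimator = "cross",
                                         test_rule = "expected5",
                                         level = 0.95) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(cases, "carrier_set"), inherits(controls, "carrier_set"))
  if (length(cases$carriers) == 0 || length(controls$carriers) == 0) {
    stop("carrier sets must be non-empty", call. = FALSE)
  }
  den_case <- if (denominator == "heterozygotes") length(cases$heterozygotes)
              else length(cases$carriers)
  den_ctrl <- if (denominator == "heterozygotes") length(controls$heterozygotes)
              else length(controls$carriers)
  haps <- sort(unique(c(cases$second_haplotypes, controls$second_haplotypes)))
  rows <- lapply(haps, function(h) {
    a <- sum(cases$second_haplotypes == h)
    c_ <- sum(controls$second_haplotypes == h)
    res <- assoc_2x2(a, den_case - a, c_, den_ctrl - c_,
                     estimator = estimator, test_rule = test_rule,
                     level = level)
    cbind(data.frame(category = h, case_n = a,
                     case_pct = 100 * a / den_case,
                     control_n = c_, control_pct = 100 * c_ / den_ctrl,
                     stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  out$case_het_total <- length(cases$heterozygotes)
  out$case_carrier_total <- length(cases$carriers)
  out$control_het_total <- length(controls$heterozygotes)
  out$control_carrier_total <- length(controls$carriers)
  rownames(out) <- NULL
  out
}

#' Anchor homozygosity test among carriers
#'
#' 2x2 table of homozygous versus heterozygous anchor carriers, cases
#' versus controls.
#'
#' @inheritParams second_haplotype_association
#' @return one-row data.frame like [assoc_2x2()] plus carrier counts.
#' @export
homozygosity_test <- function(cases, controls, estimator = "cross",
                              test_rule = "expected5", level = 0.95) {
  stopifnot(inherits(cases, "carrier_set"), inherits(controls, "carrier_set"))
  if (length(cases$carriers) == 0 || length(controls$carriers) == 0) {
    stop("carrier sets must be non-empty", call. = FALSE)
  }
  res <- assoc_2x2(length(cases$homozygotes), length(cases$heterozygotes),
                   length(controls$homozygotes), length(controls$heterozygotes),
                   estimator = estimator, test_rule = test_rule, level = level)
  cbind(data.frame(category = "anchor_homozygote",
                   case_n = length(cases$homozygotes),
                   case_pct = 100 * length(cases$homozygotes) /
                     length(cases$carriers),
                   control_n = length(controls$homozygotes),
                   control_pct = 100 * length(controls$homozygotes) /
                     length(controls$carriers),
                   stringsAsFactors = FALSE),
        res)
}
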