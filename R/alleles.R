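#' @keywords internal
new_allele <- function(locus, fields = character(), is_null = FALSE,
                       members = NULL, label = NULL) {
  structure(
    list(locus = locus, fields = fields, is_null = is_null,
         members = members, label = label),
    class = "hla_allele"
  )
}

# one numeric allele field: 1-4 digits, optional expression-suffix letter
.field_re <- "^[0-9]{1,4}[A-Z]?$"

.parse_fields <- function(body, text) {
  fields <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(fields) == 0 || any(!nzchar(fields))) {
    stop("empty allele field in '", text, "'", call. = FALSE)
  }
  if (length(fields) > 4 || any(!grepl(.field_re, fields))) {
    stop("malformed allele fields in '", text, "'", call. = FALSE)
  }
  fields
}

#' Parse an HLA allele name
#'
#' Accepts WHO-style names `LOCUS*FF:FF[:FF[:FF]]` (e.g. `"DQB1*06:02:01"`),
#' the null token `"DRBX*null"` for a non-amplified DRB3/DRB4/DRB5 slot, and
#' merged-group labels `LOCUS*A//B[//C]` (e.g. `"DQA1*03:02//03:03:01"`)
#' produced when typing batches of different resolution are pooled.
#' Formatting a parsed allele with [format()] returns the input string.
#'
#' @param text a single allele name.
#' @return an object of class `hla_allele` with elements `locus`, `fields`
#'   (character vector of numeric fields), `is_null`, and for merge groups
#'   `members` (list of field vectors) and `label`.
#' @examples
#' parse_allele("DQB1*06:02:01")
#' parse_allele("DRBX*null")
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("allele text must be a single string", call. = FALSE)
  }
  star <- regexpr("*", text, fixed = TRUE)
  if (star < 0) stop("missing '*' separator in allele '", text, "'", call. = FALSE)
  locus <- substr(text, 1, star - 1)
  body <- substr(text, star + 1, nchar(text))
  if (!locus %in% hla_locus_tokens()) {
    stop("unknown locus token '", locus, "' in allele '", text, "'", call. = FALSE)
  }
  if (identical(body, "null")) {
    if (!locus %in% drb345_tokens()) {
      stop("null call only allowed in the DRB345 slot: '", text, "'", call. = FALSE)
    }
    return(new_allele("DRBX", is_null = TRUE))
  }
  if (grepl("//", body, fixed = TRUE)) {
    parts <- strsplit(body, "//", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed merge label '", text, "'", call. = FALSE)
    members <- lapply(parts, .parse_fields, text = text)
    return(new_allele(locus, members = members, label = body))
  }
  new_allele(locus, fields = .parse_fields(body, text))
}

#' @rdname parse_allele
#' @param x an `hla_allele`.
#' @param ... unused.
#' @export
format.hla_allele <- function(x, ...) {
  if (x$is_null) return("DRBX*null")
  if (!is.null(x$members)) return(paste0(x$locus, "*", x$label))
  paste0(x$locus, "*", paste(x$fields, collapse = ":"))
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Define a merged-allele group
#'
#' When control batches are typed at different resolutions, alleles that are
#' indistinguishable across batches are counted as one group (for example
#' DQA1*03:02, 03:02:01 and 03:03:01 counted as `DQA1*03:02//03:03:01`).
#'
#' @param locus gene token the rule applies to.
#' @param members character vector (length >= 2) of member allele bodies,
#'   e.g. `c("03:02", "03:02:01", "03:03:01")`. A member also matches any
#'   allele of which it is a field-prefix, so `"03:02"` covers `03:02:01`.
#' @param label group label rendered after the locus; defaults to the
#'   members joined by `//`.
#' @return an object of class `hla_merge_rule`.
#' @export
merge_rule <- function(locus, members, label = paste(members, collapse = "//")) {
  if (!locus %in% hla_locus_tokens()) stop("unknown locus '", locus, "'", call. = FALSE)
  if (length(members) < 2) stop("a merge rule needs at least 2 members", call. = FALSE)
  fields <- lapply(members, .parse_fields, text = paste0(locus, "*", members))
  structure(list(locus = locus, members = fields, label = label),
            class = "hla_merge_rule")
}

#' Default merge rules
#'
#' Two DQA1 groups used throughout the bundled reference tables:
#' `DQA1*03:02//03:03:01` (members 03:02, 03:02:01, 03:03:01) and
#' `DQA1*02:01//02:01:01` (members 02:01, 02:01:01).
#'
#' @return list of [merge_rule()] objects.
#' @export
default_merge_rules <- function() {
  list(
    merge_rule("DQA1", c("03:02", "03:02:01", "03:03:01"),
               label = "03:02//03:03:01"),
    merge_rule("DQA1", c("02:01", "02:01:01"), label = "02:01//02:01:01")
  )
}

.rule_matches <- function(rule, allele) {
  if (rule$locus != allele$locus) return(FALSE)
  any(vapply(rule$members, function(m) {
    n <- length(m)
    n <= length(allele$fields) && identical(allele$fields[seq_len(n)], m)
  }, logical(1)))
}

#' Apply merge rules to an allele call
#'
#' Returns the merge-group call when the allele matches a rule member
#' (exact fields or the member is a field-prefix of the allele), otherwise
#' the allele unchanged. Idempotent: an allele that already is a merge
#' group passes through. An allele matching two different rules is a
#' configuration error.
#'
#' @param allele an `hla_allele`.
#' @param rules list of [merge_rule()] objects.
#' @return an `hla_allele`.
#' @export
apply_merge_rules <- function(allele, rules = default_merge_rules()) {
  stopifnot(inherits(allele, "hla_allele"))
  if (allele$is_null || !is.null(allele$members)) return(allele)
  validate_merge_rules(rules)
  hit <- vapply(rules, .rule_matches, logical(1), allele = allele)
  if (sum(hit) > 1) {
    stop("allele ", format(allele), " matches more than one merge rule",
         call. = FALSE)
  }
  if (!any(hit)) return(allele)
  r <- rules[[which(hit)]]
  new_allele(allele$locus, members = r$members, label = r$label)
}

#' @rdname apply_merge_rules
#' @export
validate_merge_rules <- function(rules) {
  if (!all(vapply(rules, inherits, logical(1), "hla_merge_rule"))) {
    stop("rules must be merge_rule objects", call. = FALSE)
  }
  keys <- unlist(lapply(rules, function(r) {
    paste0(r$locus, "*", vapply(r$members, paste, "", collapse = ":"))
  }))
  if (anyDuplicated(keys)) {
    stop("allele appears in two merge rules for the same locus: ",
         keys[duplicated(keys)][1], call. = FALSE)
  }
  invisible(rules)
}

#' Truncate an allele to a lower field resolution
#'
#' Used to compare two-field literature names (e.g. `DQB1*06:02`) with
#' three-field sequencing calls. Null calls are unchanged; merge groups are
#' truncated member-wise and collapse to a plain allele when all members
#' agree at the requested resolution.
#'
#' @param allele an `hla_allele`.
#' @param n_fields keep at most this many fields (>= 1).
#' @return an `hla_allele`.
#' @export
truncate_to_resolution <- function(allele, n_fields) {
  stopifnot(inherits(allele, "hla_allele"), n_fields >= 1)
  if (allele$is_null) return(allele)
  if (!is.null(allele$members)) {
    cut <- unique(lapply(allele$members, function(m) m[seq_len(min(n_fields, length(m)))]))
    if (length(cut) == 1) return(new_allele(allele$locus, fields = cut[[1]]))
    return(new_allele(allele$locus, members = cut,
                      label = paste(vapply(cut, paste, "", collapse = ":"),
                                    collapse = "//")))
  }
  new_allele(allele$locus, fields = allele$fields[seq_len(min(n_fields, length(allele$fields)))])
}

#' Canonicalize allele names
#'
#' Vectorized parse / merge / reformat. The result is the canonical string
#' used for all counting and comparison.
#'
#' @param x character vector of allele names.
#' @param rules merge rules applied after parsing.
#' @param n_fields optional resolution truncation.
#' @return character vector of canonical allele names (`NA` passes through).
#' @export
normalize_alleles <- function(x, rules = default_merge_rules(), n_fields = NULL) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    a <- apply_merge_rules(parse_allele(s), rules)
    if (!is.null(n_fields)) a <- truncate_to_resolution(a, n_fields)
    format(a)
  }, character(1), USE.NAMES = FALSE)
}
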