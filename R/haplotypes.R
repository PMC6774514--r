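#' Haplotype labels
#'
#' A haplotype is an ordered tuple of allele calls, one per configured slot
#' (DRB345 may be the null call), rendered as a hyphen-joined canonical
#' label, e.g.
#' `"DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01"`.
#' Allele names never contain `-`, so the label splits unambiguously.
#'
#' `hap_label()` joins allele names after sorting them into chromosomal
#' slot order; `split_haplotype()` is its inverse.
#'
#' @param alleles character vector of canonical allele names, one per slot.
#' @return `hap_label()`: a single label; `split_haplotype()`: character
#'   vector of allele names.
#' @export
hap_label <- function(alleles) {
  slots <- locus_slot(vapply(alleles, function(a) parse_allele(a)$locus, ""))
  if (anyDuplicated(slots)) {
    stop("haplotype has two alleles in slot ", slots[duplicated(slots)][1],
         call. = FALSE)
  }
  paste(alleles[order(slot_rank(slots))], collapse = "-")
}

#' @rdname hap_label
#' @param label a haplotype label.
#' @export
split_haplotype <- function(label) strsplit(label, "-", fixed = TRUE)[[1]]

#' @rdname hap_label
#' @export
hap_slots <- function(label) {
  locus_slot(vapply(split_haplotype(label), function(a) parse_allele(a)$locus, ""))
}

#' Project a haplotype onto a subset of locus slots
#'
#' Projection of extended haplotypes onto e.g. the DR block
#' (`c("DRB345", "DRB1")`) or the DQ block (`c("DQA1", "DQB1")`) yields the
#' row categories of the corresponding haplotype frequency tables.
#' Projection onto all slots is the identity.
#'
#' @param label haplotype label (or vector of labels).
#' @param locus_subset slots to keep, a subset of [hla_slots()].
#' @return character vector of projected labels.
#' @export
haplotype_label <- function(label, locus_subset = extended_slots()) {
  stopifnot(all(locus_subset %in% hla_slots()))
  vapply(label, function(l) {
    if (is.na(l)) return(NA_character_)
    alleles <- split_haplotype(l)
    keep <- hap_slots(l) %in% locus_subset
    paste(alleles[keep], collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}

#' Truncate every allele of a haplotype label to a field resolution
#'
#' Used to match haplotypes against an anchor given at a different typing
#' resolution (e.g. two-field `DQA1*01:02-DQB1*06:02` vs three-field calls).
#'
#' @param label haplotype label (or vector).
#' @param n_fields resolution passed to [truncate_to_resolution()].
#' @return character vector of truncated labels.
#' @export
hap_truncate <- function(label, n_fields) {
  vapply(label, function(l) {
    if (is.na(l)) return(NA_character_)
    paste(vapply(split_haplotype(l), function(a) {
      format(truncate_to_resolution(parse_allele(a), n_fields))
    }, ""), collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}

#' Test haplotypes against an anchor at a field resolution
#'
#' @param label character vector of haplotype labels (NA allowed).
#' @param anchor anchor haplotype label.
#' @param n_fields matching resolution (default 3).
#' @return logical vector.
#' @export
hap_matches <- function(label, anchor, n_fields = 3) {
  out <- rep(FALSE, length(label))
  ok <- !is.na(label)
  out[ok] <- hap_truncate(label[ok], n_fields) == hap_truncate(anchor, n_fields)
  out
}
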