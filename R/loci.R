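#' HLA class II locus slots
#'
#' The pipeline works over six chromosomal "slots" in display order:
#' `DRB345`, `DRB1`, `DQA1`, `DQB1`, `DPA1`, `DPB1`. The paralogous genes
#' DRB3, DRB4 and DRB5 are mutually exclusive and occupy the single
#' `DRB345` slot; a chromosome carrying none of the three renders as the
#' null call `DRBX*null`.
#'
#' @format `hla_slots()` returns a character vector of the six slot names in
#'   chromosomal order; `extended_slots()` the four slots spanned by
#'   extended haplotypes (DRB345 through DQB1).
#' @export
hla_slots <- function() c("DRB345", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

#' @rdname hla_slots
#' @export
extended_slots <- function() c("DRB345", "DRB1", "DQA1", "DQB1")

# gene tokens accepted in allele names; DRBX marks a non-amplified DRB345 slot
drb345_tokens <- function() c("DRB3", "DRB4", "DRB5", "DRBX")

hla_locus_tokens <- function() c(drb345_tokens(), "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

#' Map a locus token to its slot
#'
#' @param locus character vector of gene tokens (e.g. `"DRB4"`, `"DQB1"`).
#' @return character vector of slot names; DRB3/DRB4/DRB5/DRBX all map to
#'   `"DRB345"`.
#' @export
locus_slot <- function(locus) {
  ifelse(locus %in% drb345_tokens(), "DRB345", locus)
}

#' @rdname locus_slot
#' @param slot character vector of slot names.
#' @return `slot_rank()`: integer display rank (1 = DRB345 ... 6 = DPB1).
#' @export
slot_rank <- function(slot) match(slot, hla_slots())
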