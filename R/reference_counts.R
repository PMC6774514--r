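#' Bundled reference count tables
#'
#' Category counts from a Swedish case-control cohort of
#' Pandemrix-associated narcolepsy type 1 (31 patients, 66 first-degree
#' relatives, 636 general-population controls), bundled as plain-text
#' fixtures for validation and examples. Only the categories reported as
#' associated are listed; the remainder of each block is reconstructed
#' from the group totals by [run_from_counts()].
#'
#' Tables and their denominators:
#' \describe{
#'   \item{`alleles_gp`}{allele counts, NT1 vs GP; haplotype-slot
#'     denominators 62 and 1272.}
#'   \item{`alleles_fdr`}{allele counts, NT1 vs FDR; denominators 62 and
#'     132.}
#'   \item{`haplotypes_gp`}{DR-block, DQ-block and extended-haplotype
#'     counts, NT1 vs GP; denominators 62 and 1272.}
#'   \item{`genotypes_gp`}{extended genotype counts, NT1 vs GP; subject
#'     denominators 31 and 636.}
#'   \item{`conditional_gp`}{anchor-carrier, homozygote and
#'     second-haplotype counts among carriers, NT1 vs GP.}
#' }
#'
#' @param which table name.
#' @return data.frame with the columns of the underlying CSV; for count
#'   tables, attributes `case_total` and `control_total` carry the group
#'   denominators.
#' @export
nt1_reference_counts <- function(which = c("alleles_gp", "alleles_fdr",
                                           "haplotypes_gp", "genotypes_gp",
                                           "conditional_gp")) {
  which <- match.arg(which)
  file <- switch(which,
    alleles_gp = "nt1_allele_counts_gp.csv",
    alleles_fdr = "nt1_allele_counts_fdr.csv",
    haplotypes_gp = "nt1_haplotype_counts_gp.csv",
    genotypes_gp = "nt1_genotype_counts_gp.csv",
    conditional_gp = "nt1_conditional_counts_gp.csv")
  path <- system.file("extdata", file, package = "hlassoc", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  totals <- switch(which,
    alleles_gp = c(62L, 1272L),
    alleles_fdr = c(62L, 132L),
    haplotypes_gp = c(62L, 1272L),
    genotypes_gp = c(31L, 636L),
    conditional_gp = NULL)
  if (!is.null(totals)) {
    attr(df, "case_total") <- totals[1]
    attr(df, "control_total") <- totals[2]
  }
  df
}
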