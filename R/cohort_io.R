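#' Genotype tables
#'
#' A genotype table holds, per subject and per locus slot, an unordered pair
#' of canonical allele calls. Pairs are canonicalized (sorted) on read;
#' phase is never encoded in the input. A subject with no data at a locus
#' has an absent pair and is dropped from that locus's denominator.
#'
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (one of `NT1`, `FDR`, `GP`) and optionally `family_id`.
#' @param geno named list, one element per slot, each an n x 2 character
#'   matrix of canonical allele names (both `NA` for a missing pair).
#' @return object of class `hla_genotypes`.
#' @export
hla_genotypes <- function(subjects, geno) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         subjects$subject_id[duplicated(subjects$subject_id)][1], call. = FALSE)
  }
  if (is.null(subjects$family_id)) subjects$family_id <- NA_character_
  fam_needed <- subjects$group %in% c("NT1", "FDR")
  if (any(fam_needed & is.na(subjects$family_id))) {
    stop("NT1 and FDR subjects must carry a family_id", call. = FALSE)
  }
  if (any(!fam_needed & !is.na(subjects$family_id))) {
    stop("GP subjects must not carry a family_id", call. = FALSE)
  }
  for (s in names(geno)) {
    m <- geno[[s]]
    stopifnot(is.matrix(m), ncol(m) == 2, nrow(m) == nrow(subjects))
    one_na <- xor(is.na(m[, 1]), is.na(m[, 2]))
    if (any(one_na)) {
      stop("half-missing genotype pair at ", s, " for subject ",
           subjects$subject_id[one_na][1], call. = FALSE)
    }
    geno[[s]] <- .sort_pairs(m)
  }
  structure(list(subjects = subjects, geno = geno), class = "hla_genotypes")
}

# canonical order within each unordered pair
.sort_pairs <- function(m) {
  swap <- !is.na(m[, 1]) & m[, 2] < m[, 1]
  tmp <- m[swap, 1]
  m[swap, 1] <- m[swap, 2]
  m[swap, 2] <- tmp
  dimnames(m) <- list(NULL, c("a1", "a2"))
  m
}

#' @export
print.hla_genotypes <- function(x, ...) {
  cat("<hla_genotypes> ", nrow(x$subjects), " subjects (",
      paste(names(table(x$subjects$group)), table(x$subjects$group),
            sep = "=", collapse = ", "),
      "), slots: ", paste(names(x$geno), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of typed subjects per group at a slot
#' @param g an `hla_genotypes`.
#' @param slot slot name.
#' @return named integer vector (groups).
#' @export
typed_per_group <- function(g, slot) {
  ok <- !is.na(g$geno[[slot]][, 1])
  tab <- table(factor(g$subjects$group[ok]))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a subject genotype table
#'
#' Tab-separated file, one row per subject, with a header naming
#' `subject_id`, `group`, optional `family_id`, and two columns
#' `<SLOT>_1`, `<SLOT>_2` per locus slot. Allele values may be full names
#' (`DQB1*06:02:01`) or bare field strings (`06:02:01`), except in the
#' `DRB345` slot where the gene must be explicit (`DRB4*01:03:01` or
#' `DRBX*null`). Empty strings mark a missing pair (both columns must be
#' empty). Merge rules are applied on read and pairs canonicalized.
#'
#' @param path file path.
#' @param rules merge rules (see [merge_rule()]).
#' @return an [hla_genotypes()] object.
#' @export
read_genotype_table <- function(path, rules = default_merge_rules()) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = c("", "NA"))
  if (!all(c("subject_id", "group") %in% names(raw))) {
    stop("missing required column subject_id / group in ", path, call. = FALSE)
  }
  slot_cols <- grep("^(.+)_([12])$", names(raw), value = TRUE)
  slots <- intersect(hla_slots(), unique(sub("_[12]$", "", slot_cols)))
  if (length(slots) == 0) stop("no <SLOT>_1/<SLOT>_2 columns found in ", path, call. = FALSE)
  subjects <- data.frame(subject_id = raw$subject_id, group = raw$group,
                         family_id = if ("family_id" %in% names(raw))
                           raw$family_id else NA_character_,
                         stringsAsFactors = FALSE)
  geno <- list()
  for (s in slots) {
    c1 <- raw[[paste0(s, "_1")]]
    c2 <- raw[[paste0(s, "_2")]]
    if (is.null(c1) || is.null(c2)) stop("missing column for slot ", s, call. = FALSE)
    geno[[s]] <- cbind(.read_allele_col(c1, s, rules), .read_allele_col(c2, s, rules))
  }
  hla_genotypes(subjects, geno)
}

.read_allele_col <- function(x, slot, rules) {
  x <- trimws(ifelse(is.na(x), "", x))
  x[x == ""] <- NA_character_
  bare <- !is.na(x) & !grepl("*", x, fixed = TRUE)
  if (any(bare)) {
    if (slot == "DRB345") {
      stop("DRB345 slot values must carry an explicit gene token (got '",
           x[bare][1], "')", call. = FALSE)
    }
    x[bare] <- paste0(slot, "*", x[bare])
  }
  normalize_alleles(x, rules)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; reading the written file back yields
#' an identical object.
#'
#' @param g an `hla_genotypes`.
#' @param path output path (tab-separated, UTF-8, LF).
#' @export
write_genotype_table <- function(g, path) {
  out <- g$subjects[c("subject_id", "group", "family_id")]
  for (s in names(g$geno)) {
    out[[paste0(s, "_1")]] <- g$geno[[s]][, 1]
    out[[paste0(s, "_2")]] <- g$geno[[s]][, 2]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a PED-like pedigree file
#'
#' Whitespace-separated, six columns: family id, subject id, father id
#' (0 = unknown), mother id (0 = unknown), sex, affected status
#' (2 = affected). Parent ids must name subjects in the same family; no
#' subject may be its own ancestor.
#'
#' @param path file path.
#' @return data.frame of class `hla_pedigree` with columns `family_id`,
#'   `subject_id`, `father_id`, `mother_id` (`NA` = unknown), `sex`,
#'   `affected` (logical).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, colClasses = "character")
  if (ncol(raw) != 6) stop("pedigree file must have 6 columns", call. = FALSE)
  names(raw) <- c("family_id", "subject_id", "father_id", "mother_id",
                  "sex", "affected")
  ped <- data.frame(
    family_id = raw$family_id, subject_id = raw$subject_id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex = raw$sex, affected = raw$affected == "2",
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$subject_id)) {
    stop("duplicate subject in pedigree: ",
         ped$subject_id[duplicated(ped$subject_id)][1], call. = FALSE)
  }
  for (i in seq_len(nrow(ped))) {
    for (p in c("father_id", "mother_id")) {
      pid <- ped[[p]][i]
      if (is.na(pid)) next
      j <- match(pid, ped$subject_id)
      if (is.na(j)) {
        stop("parent ", pid, " of ", ped$subject_id[i],
             " not in pedigree and not 0", call. = FALSE)
      }
      if (ped$family_id[j] != ped$family_id[i]) {
        stop("parent ", pid, " of ", ped$subject_id[i],
             " is in a different family", call. = FALSE)
      }
    }
  }
  .check_acyclic(ped)
  class(ped) <- c("hla_pedigree", "data.frame")
  ped
}

.check_acyclic <- function(ped) {
  for (s in ped$subject_id) {
    seen <- character()
    frontier <- s
    while (length(frontier)) {
      i <- match(frontier, ped$subject_id)
      parents <- stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
      if (s %in% parents) {
        stop("subject ", s, " is its own ancestor", call. = FALSE)
      }
      parents <- setdiff(parents, seen)
      seen <- c(seen, parents)
      frontier <- parents
    }
  }
  invisible(TRUE)
}

# printed-table number formats: percentages 1 dp, OR/CI 2 dp, p-values in
# scientific notation with 3 significant digits
fmt_pct <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 1))
fmt_or <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 2))
fmt_p <- function(x) ifelse(is.na(x), "", formatC(x, format = "E", digits = 2))

#' Write an association result table
#'
#' Comma-separated output with deterministic row order (descending case
#' frequency, ties broken by category label) and the display formats of the
#' printed tables: percentages to 1 decimal, OR and CI bounds to 2 decimals,
#' p-values in scientific notation with 3 significant digits. If the result
#' carries RPE columns (`p_round1`, `p_round2`, ...) they are formatted the
#' same way. An empty result set yields a header-only file.
#'
#' @param results data.frame as returned by [associate_all()], optionally
#'   augmented with RPE round columns.
#' @param path output path.
#' @export
write_association_table <- function(results, path) {
  if (nrow(results)) {
    results <- results[order(-results$case_pct, results$category), ]
  }
  out <- results
  for (nm in names(out)) {
    if (nm %in% c("case_pct", "control_pct")) out[[nm]] <- fmt_pct(out[[nm]])
    if (nm %in% c("or", "ci_low", "ci_high")) out[[nm]] <- fmt_or(out[[nm]])
    if (nm == "p" || grepl("^p_round", nm)) out[[nm]] <- fmt_p(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write per-subject phased haplotypes
#'
#' @param phased data.frame with columns `subject_id`, `hap1`, `hap2`,
#'   `provenance`, `ambiguity_count`.
#' @param path output path (tab-separated).
#' @export
write_haplotype_table <- function(phased, path) {
  cols <- c("subject_id", "hap1", "hap2", "provenance", "ambiguity_count")
  utils::write.table(phased[intersect(cols, names(phased))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
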