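#' Phase a nuclear family by inheritance (descent)
#'
#' Exhaustively enumerates per-locus transmission assignments: each
#' parent's unordered genotype pairs are split into two intact haplotypes
#' (no recombination within the block), and each child must receive exactly
#' one parental haplotype from each parent. A member whose haplotype pair
#' is identical across all transmission-consistent assignments is phased
#' (`provenance = "descent"`, `ambiguity_count = 1`); otherwise it is
#' `"unresolved"` with the number of admissible pairs. Because transmitted
#' haplotypes are intact, no recombinant haplotype is ever invented.
#'
#' Families must be nuclear: at most one founder couple; children carry
#' both parent ids or none. Members without genotypes at the requested
#' slots are skipped.
#'
#' @param family one family's rows of an [read_pedigree()] data.frame.
#' @param genotypes an [hla_genotypes()] covering the family members.
#' @param slots locus slots to phase over (default [extended_slots()]).
#' @return data.frame: `subject_id`, `hap1`, `hap2` (canonical labels,
#'   `hap1 <= hap2`; `NA` when unresolved), `provenance`,
#'   `ambiguity_count`.
#' @export
phase_by_descent <- function(family, genotypes, slots = extended_slots()) {
  stopifnot(length(unique(family$family_id)) == 1)
  fam_id <- family$family_id[1]
  slots <- intersect(slots, names(genotypes$geno))
  g <- .subject_slot_pairs(genotypes, slots)
  members <- intersect(family$subject_id, rownames(g$a1))
  members <- members[!apply(is.na(g$a1[members, , drop = FALSE]), 1, any)]
  if (length(members) < 2) {
    stop("family ", fam_id, " needs genotypes for at least 2 members",
         call. = FALSE)
  }
  fam <- family[match(members, family$subject_id), ]

  half <- xor(is.na(fam$father_id), is.na(fam$mother_id))
  if (any(half)) {
    stop("family ", fam_id, ": subject ", fam$subject_id[half][1],
         " has only one parent recorded; nuclear families need both or none",
         call. = FALSE)
  }
  children <- fam$subject_id[!is.na(fam$father_id)]
  couples <- unique(fam[!is.na(fam$father_id), c("father_id", "mother_id")])
  if (nrow(couples) > 1) {
    stop("family ", fam_id, " has more than one founder couple; ",
         "only nuclear families are supported", call. = FALSE)
  }
  splits <- lapply(members, function(s) .hap_splits(g$a1[s, ], g$a2[s, ]))
  names(splits) <- members

  out <- data.frame(subject_id = members, hap1 = NA_character_,
                    hap2 = NA_character_, provenance = "unresolved",
                    ambiguity_count = vapply(splits, length, 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  if (length(children) == 0 || nrow(couples) == 0) {
    # founders only: no transmission constraints
    return(.finalize_descent(out, splits, lapply(splits, seq_along)))
  }
  fa <- couples$father_id[1]
  mo <- couples$mother_id[1]
  for (p in c(fa, mo)) {
    if (!p %in% members) {
      stop("family ", fam_id, ": parent ", p, " has no genotype data",
           call. = FALSE)
    }
  }

  # admissible split indices per member, accumulated over feasible
  # father x mother phase combinations
  admissible <- lapply(splits, function(s) integer())
  feasible_any <- FALSE
  for (fi in seq_along(splits[[fa]])) {
    fhaps <- splits[[fa]][[fi]]
    for (mi in seq_along(splits[[mo]])) {
      mhaps <- splits[[mo]][[mi]]
      ok <- TRUE
      child_ok <- list()
      for (ch in children) {
        cs <- which(vapply(splits[[ch]], .child_compatible, logical(1),
                           fhaps = fhaps, mhaps = mhaps))
        if (length(cs) == 0) { ok <- FALSE; break }
        child_ok[[ch]] <- cs
      }
      if (!ok) next
      feasible_any <- TRUE
      admissible[[fa]] <- union(admissible[[fa]], fi)
      admissible[[mo]] <- union(admissible[[mo]], mi)
      for (ch in children) {
        admissible[[ch]] <- union(admissible[[ch]], child_ok[[ch]])
      }
    }
  }
  if (!feasible_any) {
    .mendel_error(fam_id, fam, g, children, fa, mo)
  }
  # members outside the couple+children core (should not occur in nuclear
  # families) keep all their splits
  for (s in members) {
    if (length(admissible[[s]]) == 0) admissible[[s]] <- seq_along(splits[[s]])
  }
  .finalize_descent(out, splits, admissible)
}

.finalize_descent <- function(out, splits, admissible) {
  for (i in seq_len(nrow(out))) {
    s <- out$subject_id[i]
    adm <- admissible[[s]]
    out$ambiguity_count[i] <- length(adm)
    if (length(adm) == 1) {
      pair <- sort(vapply(splits[[s]][[adm]], function(h) paste(h, collapse = "-"), ""))
      out$hap1[i] <- pair[1]
      out$hap2[i] <- pair[2]
      out$provenance[i] <- "descent"
    }
  }
  out
}

# all distinct unordered splits of a multi-locus genotype into two intact
# haplotypes: 2^(h-1) for h heterozygous loci (1 when fully homozygous).
# each split is a list of two allele vectors (in slot order).
.hap_splits <- function(a1, a2) {
  het <- which(a1 != a2)
  if (length(het) == 0) return(list(list(a1, a2)))
  free <- het[-1]  # fix the first het locus to kill the hap1/hap2 swap
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(free)))
  lapply(seq_len(max(nrow(combos), 1)), function(k) {
    h1 <- a1
    h2 <- a2
    if (length(free)) {
      flip <- free[unlist(combos[k, ])]
      h1[flip] <- a2[flip]
      h2[flip] <- a1[flip]
    }
    list(h1, h2)
  })
}

# child split {c1,c2} is transmission-consistent iff one haplotype matches a
# paternal and the other a maternal haplotype
.child_compatible <- function(cs, fhaps, mhaps) {
  c1 <- cs[[1]]; c2 <- cs[[2]]
  eq <- function(x, y) identical(unname(x), unname(y))
  in_f <- c(eq(c1, fhaps[[1]]) || eq(c1, fhaps[[2]]),
            eq(c2, fhaps[[1]]) || eq(c2, fhaps[[2]]))
  in_m <- c(eq(c1, mhaps[[1]]) || eq(c1, mhaps[[2]]),
            eq(c2, mhaps[[1]]) || eq(c2, mhaps[[2]]))
  (in_f[1] && in_m[2]) || (in_f[2] && in_m[1])
}

.mendel_error <- function(fam_id, fam, g, children, fa, mo) {
  # locate a per-locus violation for the error message
  for (ch in children) {
    for (j in seq_len(ncol(g$a1))) {
      cp <- c(g$a1[ch, j], g$a2[ch, j])
      fp <- c(g$a1[fa, j], g$a2[fa, j])
      mp <- c(g$a1[mo, j], g$a2[mo, j])
      ok <- any(vapply(seq_len(2), function(k) {
        cp[k] %in% fp && cp[3 - k] %in% mp
      }, logical(1)))
      if (!ok) {
        stop("Mendelian inconsistency in family ", fam_id, ", subject ", ch,
             ", locus ", colnames(g$a1)[j], call. = FALSE)
      }
    }
  }
  stop("Mendelian inconsistency in family ", fam_id,
       " (no transmission-consistent multi-locus phase)", call. = FALSE)
}

# subject x slot allele matrices (pair members a1 <= a2), rownames subject_id
.subject_slot_pairs <- function(genotypes, slots) {
  ids <- genotypes$subjects$subject_id
  a1 <- do.call(cbind, lapply(slots, function(s) genotypes$geno[[s]][, 1]))
  a2 <- do.call(cbind, lapply(slots, function(s) genotypes$geno[[s]][, 2]))
  dimnames(a1) <- dimnames(a2) <- list(ids, slots)
  list(a1 = a1, a2 = a2)
}

#' Phase all families of a cohort by descent
#'
#' @param genotypes an [hla_genotypes()].
#' @param pedigree an [read_pedigree()] data.frame.
#' @param slots locus slots to phase.
#' @return data.frame as [phase_by_descent()], rows for every pedigree
#'   member with genotypes.
#' @export
phase_families <- function(genotypes, pedigree, slots = extended_slots()) {
  fams <- split(pedigree, pedigree$family_id)
  out <- lapply(fams, phase_by_descent, genotypes = genotypes, slots = slots)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
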