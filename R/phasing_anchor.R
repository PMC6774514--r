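#' Known-haplotype set
#'
#' Extended haplotypes observed so far, with the number of chromosome
#' copies assigned to each; ordering is by descending count, ties by
#' label.
#'
#' @param haplotype character vector of haplotype labels.
#' @param count integer copy counts (>= 0).
#' @return data.frame of class `known_haplotypes`.
#' @export
known_haplotypes <- function(haplotype = character(), count = integer()) {
  stopifnot(length(haplotype) == length(count), all(count >= 0),
            !anyDuplicated(haplotype))
  df <- data.frame(haplotype = haplotype, count = as.integer(count),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$haplotype), ]
  rownames(df) <- NULL
  class(df) <- c("known_haplotypes", "data.frame")
  df
}

#' Assemble extended haplotypes of unrelated subjects around an anchor
#'
#' The four-step scheme used to phase unrelated subjects:
#' \enumerate{
#'   \item subjects homozygous at every slot are phased trivially
#'     (`provenance = "homozygote"`);
#'   \item carriers of the anchor haplotype are phased by subtraction --
#'     the anchor alleles form one haplotype, the remaining alleles the
#'     second, which joins the known set (`"anchor_subtraction"`);
#'   \item remaining subjects are processed in passes until a fixed point:
#'     a subject whose genotype decomposes as one known haplotype plus a
#'     remainder is phased (`"known_match"`), the remainder joining the
#'     known set; with several admissible decompositions the one
#'     containing the most frequent known haplotype is taken (ties by
#'     label) and the number of admissible pairs is recorded in
#'     `ambiguity_count`;
#'   \item a subject whose two candidate haplotypes match the same
#'     DRB3/4/5 allele (and not the subject's other one) is resolved by
#'     assigning the matched allele to the more common haplotype
#'     (`"conflict_rule"`).
#' }
#' Subjects with no decomposition stay `"unresolved"` (hap labels `NA`);
#' they are excluded from haplotype-level counts but remain in allele-level
#' counts.
#'
#' @param genotypes an [hla_genotypes()] of unrelated subjects (subjects
#'   with missing data at any requested slot are left unresolved).
#' @param anchor anchor haplotype label over the same slots, e.g.
#'   `"DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01"`.
#' @param known optional [known_haplotypes()] to seed the set (e.g.
#'   haplotypes phased by descent in families).
#' @param slots locus slots of the extended haplotype.
#' @param max_passes safety bound on step-3 passes.
#' @return list: `phased` (data.frame `subject_id`, `hap1`, `hap2`,
#'   `provenance`, `ambiguity_count`), `known` (updated
#'   [known_haplotypes()]).
#' @export
assemble_by_anchor <- function(genotypes, anchor, known = NULL,
                               slots = extended_slots(), max_passes = 100) {
  slots <- intersect(slots, names(genotypes$geno))
  g <- .subject_slot_pairs(genotypes, slots)
  n <- nrow(g$a1)
  ids <- rownames(g$a1)
  anchor_alleles <- split_haplotype(anchor)
  anchor_slots <- hap_slots(anchor)
  if (!setequal(anchor_slots, slots)) {
    stop("anchor must cover the slots ", paste(slots, collapse = ", "),
         call. = FALSE)
  }
  anchor_alleles <- anchor_alleles[match(slots, anchor_slots)]
  anchor_key <- paste(anchor_alleles, collapse = "-")

  counts <- stats::setNames(integer(), character())
  if (!is.null(known)) counts <- stats::setNames(known$count, known$haplotype)
  if (!anchor_key %in% names(counts)) counts[anchor_key] <- 0L
  add_copy <- function(key) {
    if (is.null(counts[key]) || is.na(counts[key])) counts[key] <<- 0L
    counts[key] <<- counts[key] + 1L
  }

  hap1 <- rep(NA_character_, n)
  hap2 <- rep(NA_character_, n)
  prov <- rep("unresolved", n)
  amb <- rep(NA_integer_, n)
  complete <- !apply(is.na(g$a1), 1, any)
  open <- which(complete)

  # step 1: homozygotes
  hom <- open[rowSums(g$a1[open, , drop = FALSE] !=
                        g$a2[open, , drop = FALSE]) == 0]
  for (i in hom) {
    key <- paste(g$a1[i, ], collapse = "-")
    hap1[i] <- hap2[i] <- key
    prov[i] <- "homozygote"
    amb[i] <- 1L
    add_copy(key); add_copy(key)
  }
  open <- setdiff(open, hom)

  # step 2: anchor carriers phased by subtraction
  carries <- open[vapply(open, function(i) {
    all(anchor_alleles == g$a1[i, ] | anchor_alleles == g$a2[i, ])
  }, logical(1))]
  for (i in carries) {
    rem <- ifelse(g$a1[i, ] == anchor_alleles, g$a2[i, ], g$a1[i, ])
    key <- paste(rem, collapse = "-")
    pair <- sort(c(anchor_key, key))
    hap1[i] <- pair[1]; hap2[i] <- pair[2]
    prov[i] <- "anchor_subtraction"
    amb[i] <- 1L
    add_copy(anchor_key); add_copy(key)
  }
  open <- setdiff(open, carries)

  # steps 3-4: iterative decomposition against the known set
  drb_col <- match("DRB345", slots)
  for (pass in seq_len(max_passes)) {
    progressed <- FALSE
    # known-set snapshot for this pass; copies assigned during the pass
    # update the counts, newly discovered remainders enter next pass
    keys <- names(counts)
    mats <- strsplit(keys, "-", fixed = TRUE)
    keep <- lengths(mats) == length(slots)
    keys <- keys[keep]
    mats <- mats[keep]
    for (i in open) {
      if (prov[i] != "unresolved") next
      res <- .decompose_subject(g$a1[i, ], g$a2[i, ], keys, mats, counts,
                                drb_col)
      if (is.null(res)) next
      hap1[i] <- res$pair[1]; hap2[i] <- res$pair[2]
      prov[i] <- res$provenance
      amb[i] <- res$ambiguity
      add_copy(res$pair[1]); add_copy(res$pair[2])
      progressed <- TRUE
    }
    open <- open[prov[open] == "unresolved"]
    if (!progressed || length(open) == 0) break
  }

  # unresolved: ambiguity is the number of admissible splits absent any
  # population knowledge
  for (i in which(prov == "unresolved")) {
    if (!complete[i]) { amb[i] <- NA_integer_; next }
    h <- sum(g$a1[i, ] != g$a2[i, ])
    amb[i] <- as.integer(2^max(h - 1, 0))
  }

  phased <- data.frame(subject_id = ids, hap1 = hap1, hap2 = hap2,
                       provenance = prov, ambiguity_count = amb,
                       stringsAsFactors = FALSE)
  list(phased = phased,
       known = known_haplotypes(names(counts), unname(counts)))
}

# one subject's decomposition against the known set.  a1/a2: allele vectors
# (pair-sorted per slot).  keys/mats: known haplotype labels and their
# allele vectors.  counts: named copy counts.  returns NULL when no
# decomposition exists, else list(pair, provenance, ambiguity).
.decompose_subject <- function(a1, a2, keys, mats, counts, drb_col) {
  pairs <- character()
  for (k in seq_along(keys)) {
    h <- mats[[k]]
    if (all(h == a1 | h == a2)) {
      rem <- ifelse(h == a1, a2, a1)
      pairs <- c(pairs, paste(sort(c(keys[k], paste(rem, collapse = "-"))),
                              collapse = "\r"))
    }
  }
  pairs <- unique(pairs)
  if (length(pairs) == 0) return(NULL)
  if (length(pairs) == 1) {
    return(list(pair = strsplit(pairs, "\r", fixed = TRUE)[[1]],
                provenance = "known_match", ambiguity = 1L))
  }
  # several admissible decompositions: prefer the one containing the most
  # frequent known haplotype; ties by label
  best <- vapply(pairs, function(p) {
    hs <- strsplit(p, "\r", fixed = TRUE)[[1]]
    max(counts[hs], 0, na.rm = TRUE)
  }, 0)
  sel <- strsplit(pairs[order(-best, pairs)][1], "\r", fixed = TRUE)[[1]]
  # step-4 conflict rule: when the decompositions agree everywhere except
  # the DRB3/4/5 assignment (both candidate haplotypes match the same
  # DRB3/4/5 allele), the frequency preference above is exactly the rule
  # "assign the matched allele to the more common haplotype" and the phase
  # is considered resolved
  if (!is.na(drb_col)) {
    proj <- unique(vapply(pairs, function(p) {
      hs <- strsplit(p, "\r", fixed = TRUE)[[1]]
      paste(sort(vapply(hs, function(h) {
        paste(strsplit(h, "-", fixed = TRUE)[[1]][-drb_col], collapse = "-")
      }, "")), collapse = "\r")
    }, ""))
    if (length(proj) == 1 && a1[drb_col] != a2[drb_col]) {
      return(list(pair = sel, provenance = "conflict_rule", ambiguity = 1L))
    }
  }
  list(pair = sel, provenance = "known_match", ambiguity = length(pairs))
}
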