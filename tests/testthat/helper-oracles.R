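# Independent oracles used across test files.  These re-derive expected
# results from first principles and must stay independent of the package
# implementation paths they check.

# Fisher two-sided p by exhaustive enumeration of the hypergeometric
# support: sum of probabilities of all tables with the observed margins
# whose probability does not exceed the observed one (with the same
# relative tolerance R uses for that comparison).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c          # first-column margin
  r1 <- a + b         # first-row margin
  n <- b + d
  support <- max(0, r1 - n):min(r1, m)
  probs <- stats::dhyper(support, m, n, r1)
  p_obs <- stats::dhyper(a, m, n, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force nuclear-family phasing: enumerate every ordered split of
# every member (2^L each) and keep combinations where each child receives
# one paternal and one maternal haplotype.  Returns, per member, the set
# of admissible unordered haplotype pairs (as "h1|h2" keys).
#
# geno: list per member of a 2-column matrix (loci x 2 alleles, unordered)
brute_family_phase <- function(father, mother, children) {
  ordered_splits <- function(g) {
    L <- nrow(g)
    combos <- as.matrix(expand.grid(rep(list(1:2), L)))
    lapply(seq_len(nrow(combos)), function(k) {
      h1 <- g[cbind(seq_len(L), combos[k, ])]
      h2 <- g[cbind(seq_len(L), 3 - combos[k, ])]
      list(h1, h2)
    })
  }
  fs <- ordered_splits(father)
  ms <- ordered_splits(mother)
  css <- lapply(children, ordered_splits)
  key <- function(h) paste(h, collapse = "-")
  pair_key <- function(s) paste(sort(c(key(s[[1]]), key(s[[2]]))), collapse = "|")
  n_members <- 2 + length(children)
  admissible <- replicate(n_members, character(), simplify = FALSE)
  for (f in fs) {
    for (m in ms) {
      fk <- c(key(f[[1]]), key(f[[2]]))
      mk <- c(key(m[[1]]), key(m[[2]]))
      kid_sets <- vector("list", length(children))
      ok <- TRUE
      for (ci in seq_along(children)) {
        hits <- Filter(function(s) {
          k1 <- key(s[[1]]); k2 <- key(s[[2]])
          (k1 %in% fk && k2 %in% mk) || (k2 %in% fk && k1 %in% mk)
        }, css[[ci]])
        if (length(hits) == 0) { ok <- FALSE; break }
        kid_sets[[ci]] <- unique(vapply(hits, pair_key, ""))
      }
      if (!ok) next
      admissible[[1]] <- union(admissible[[1]], pair_key(f))
      admissible[[2]] <- union(admissible[[2]], pair_key(m))
      for (ci in seq_along(children)) {
        admissible[[2 + ci]] <- union(admissible[[2 + ci]], kid_sets[[ci]])
      }
    }
  }
  admissible
}

# unordered haplotype-pair key for comparing phased output with truth
pair_key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2), sep = "|")

# genotype object for a handful of subjects given per-slot allele pairs.
# pairs: named list slot -> list of c(a1, a2) per subject
toy_genotypes <- function(pairs, group = "GP", family_id = NA_character_) {
  n <- length(pairs[[1]])
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(group, length.out = n),
    family_id = rep(family_id, length.out = n),
    stringsAsFactors = FALSE
  )
  geno <- lapply(pairs, function(p) do.call(rbind, p))
  hla_genotypes(subjects, geno)
}

# reference anchor used throughout
test_anchor <- function() {
  "DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01"
}
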