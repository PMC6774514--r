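#' Haplotype pool
#'
#' A frequency-weighted list of extended haplotypes; the generative object
#' of the synthetic cohort module. Population chromosomes are independent
#' draws from the pool (Hardy-Weinberg equilibrium), which encodes the
#' strong DR-DQ linkage disequilibrium directly: only the listed allele
#' combinations exist.
#'
#' @param haplotype character vector of haplotype labels (unique).
#' @param freq frequencies (non-negative, summing to 1 within 1e-9; they
#'   are renormalized to machine precision).
#' @return data.frame of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotype, freq) {
  stopifnot(length(haplotype) == length(freq), !anyDuplicated(haplotype),
            all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("pool frequencies must sum to 1 (got ", format(sum(freq)), ")",
         call. = FALSE)
  }
  df <- data.frame(haplotype = haplotype, freq = freq / sum(freq),
                   stringsAsFactors = FALSE)
  class(df) <- c("haplotype_pool", "data.frame")
  df
}

#' Default 16-haplotype pool
#'
#' Sixteen extended DRB3/4/5-DRB1-DQA1-DQB1 haplotypes with general
#' population frequencies. The risk (anchor) haplotype is at 15.3% and the
#' three other haplotype-block frequencies reported for the reference
#' control cohort are used where available (3.1%, 4.0%, 3.2%); the
#' remaining haplotypes are the common Northern-European DR-DQ linkage
#' blocks with frequencies chosen to reproduce realistic allele marginals
#' (e.g. DRB4*01:03:01 near 24%) and to sum to 1 exactly.
#'
#' @return a [haplotype_pool()].
#' @export
default_pool <- function() {
  haps <- c(
    "DRB5*01:01:01-DRB1*15:01:01-DQA1*01:02:01-DQB1*06:02:01",
    "DRB4*01:03:01-DRB1*04:01:01-DQA1*03:02//03:03:01-DQB1*03:01:01",
    "DRB3*03:01:01-DRB1*13:02:01-DQA1*01:02:01-DQB1*06:04:01",
    "DRB4*01:03:01-DRB1*07:01:01-DQA1*02:01//02:01:01-DQB1*02:02:01",
    "DRB3*01:01:02-DRB1*03:01:01-DQA1*05:01:01-DQB1*02:01:01",
    "DRBX*null-DRB1*01:01:01-DQA1*01:01:01-DQB1*05:01:01",
    "DRB3*02:02:01-DRB1*11:01:01-DQA1*05:05:01-DQB1*03:01:01",
    "DRB3*01:01:02-DRB1*13:01:01-DQA1*01:03:01-DQB1*06:03:01",
    "DRB4*01:03:01-DRB1*04:04:01-DQA1*03:01:01-DQB1*03:02:01",
    "DRBX*null-DRB1*08:01:01-DQA1*04:01:01-DQB1*04:02:01",
    "DRB3*02:02:01-DRB1*12:01:01-DQA1*05:05:01-DQB1*03:01:01",
    "DRB5*02:02:01-DRB1*16:01:01-DQA1*01:02:02-DQB1*05:02:01",
    "DRB4*01:03:01-DRB1*09:01:02-DQA1*03:02//03:03:01-DQB1*03:03:01",
    "DRB3*01:01:02-DRB1*14:01:01-DQA1*01:04:01-DQB1*05:03:01",
    "DRBX*null-DRB1*10:01:01-DQA1*01:05:01-DQB1*05:01:01",
    "DRB4*01:03:01-DRB1*04:02:01-DQA1*03:01:01-DQB1*03:02:01"
  )
  freq <- c(0.153, 0.031, 0.040, 0.032, 0.130, 0.115, 0.075, 0.060, 0.085,
            0.052, 0.032, 0.045, 0.040, 0.038, 0.016, 0.056)
  haplotype_pool(haps, freq)
}

#' Multiplicative genotype risk model
#'
#' Disease probability of a genotype `(h1, h2)` is
#' `baseline * rr[h1] * rr[h2]`, with per-haplotype relative risk 1 when
#' unlisted. Optionally, `second_rr` multiplies the risk of genotypes with
#' exactly one copy of `anchor` whose other haplotype is listed -- the
#' structure needed to encode a risk-modifying second haplotype.
#'
#' @param rr named vector of per-haplotype relative risks (> 0).
#' @param baseline baseline disease probability.
#' @param anchor anchor haplotype label (required when `second_rr` given).
#' @param second_rr named vector of extra risk for designated second
#'   haplotypes given one anchor copy.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(rr = NULL, baseline = 0.01, anchor = NULL,
                       second_rr = NULL) {
  if (!is.null(rr) && (is.null(names(rr)) || any(rr <= 0))) {
    stop("rr must be a named vector of positive relative risks", call. = FALSE)
  }
  if (!is.null(second_rr) && is.null(anchor)) {
    stop("second_rr requires an anchor", call. = FALSE)
  }
  stopifnot(baseline > 0, baseline <= 1)
  structure(list(rr = rr, baseline = baseline, anchor = anchor,
                 second_rr = second_rr), class = "risk_model")
}

#' @rdname risk_model
#' @param model a `risk_model`.
#' @param h1,h2 haplotype label vectors (a genotype per element pair).
#' @return `genotype_risk()`: numeric disease probabilities.
#' @export
genotype_risk <- function(model, h1, h2) {
  stopifnot(inherits(model, "risk_model"))
  look <- function(h) {
    r <- rep(1, length(h))
    if (!is.null(model$rr)) {
      hit <- match(h, names(model$rr))
      r[!is.na(hit)] <- model$rr[hit[!is.na(hit)]]
    }
    r
  }
  risk <- model$baseline * look(h1) * look(h2)
  if (!is.null(model$second_rr)) {
    is1 <- h1 == model$anchor
    is2 <- h2 == model$anchor
    one_copy <- xor(is1, is2)
    other <- ifelse(is1, h2, h1)
    hit <- match(other, names(model$second_rr))
    mod <- one_copy & !is.na(hit)
    risk[mod] <- risk[mod] * model$second_rr[hit[mod]]
  }
  if (any(risk > 1)) {
    stop("risk model yields genotype probabilities > 1", call. = FALSE)
  }
  risk
}

# split pool haplotypes into an allele matrix (one column per slot)
.pool_alleles <- function(pool) {
  mat <- do.call(rbind, strsplit(pool$haplotype, "-", fixed = TRUE))
  colnames(mat) <- hap_slots(pool$haplotype[1])
  mat
}

# genotype object from per-subject haplotype label pairs
.genotypes_from_pairs <- function(subjects, h1, h2, pool_alleles) {
  slots <- colnames(pool_alleles)
  labels <- rownames(pool_alleles)
  i1 <- match(h1, labels)
  i2 <- match(h2, labels)
  geno <- lapply(slots, function(s) {
    cbind(pool_alleles[i1, s], pool_alleles[i2, s])
  })
  names(geno) <- slots
  hla_genotypes(subjects, geno)
}

.truth_df <- function(ids, h1, h2) {
  swap <- h2 < h1
  tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
  data.frame(subject_id = ids, true_hap1 = h1, true_hap2 = h2,
             stringsAsFactors = FALSE)
}

#' Sample an unrelated population cohort from a pool
#'
#' Each subject is two independent chromosome draws from the pool
#' (Hardy-Weinberg sampling). The genotype table is emitted unphased
#' (pairs canonicalized); the generating phase is retained separately as
#' ground truth.
#'
#' @param pool a [haplotype_pool()].
#' @param n number of subjects.
#' @param seed optional integer seed (all outputs are pure functions of
#'   parameters and seed).
#' @param group group label for the subjects (default `"GP"`).
#' @param id_prefix subject id prefix.
#' @return list: `genotypes` ([hla_genotypes()]), `truth` (data.frame
#'   `subject_id`, `true_hap1`, `true_hap2`).
#' @export
sample_population <- function(pool, n, seed = NULL, group = "GP",
                              id_prefix = group) {
  stopifnot(inherits(pool, "haplotype_pool"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(nrow(pool), 2 * n, replace = TRUE,
                           prob = pool$freq), ncol = 2)
  h1 <- pool$haplotype[idx[, 1]]
  h2 <- pool$haplotype[idx[, 2]]
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  pa <- .pool_alleles(pool)
  rownames(pa) <- pool$haplotype
  subjects <- data.frame(subject_id = ids, group = group,
                         family_id = NA_character_, stringsAsFactors = FALSE)
  list(genotypes = .genotypes_from_pairs(subjects, h1, h2, pa),
       truth = .truth_df(ids, h1, h2))
}

#' Sample nuclear families with Mendelian transmission
#'
#' Founder couples are drawn as in [sample_population()]; each child
#' inherits one intact haplotype per parent, uniformly at random. The
#' first child of each family is labelled the proband (`group = "NT1"`,
#' affected); parents and further children are `"FDR"`. No ascertainment
#' is applied here -- see [simulate_study()] for risk-based proband
#' ascertainment.
#'
#' @param pool a [haplotype_pool()].
#' @param n_families number of families.
#' @param n_children children per family (>= 1; the first is the proband).
#' @param seed optional integer seed.
#' @return list: `genotypes`, `pedigree` (class `hla_pedigree`), `truth`.
#' @export
sample_families <- function(pool, n_families, n_children = 1, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), n_families > 0, n_children >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- .draw_families(pool, n_families, n_children)
  .families_to_cohort(pool, draws)
}

# raw family draws: per family father/mother haplotype pairs and per child
# transmitted indices
.draw_families <- function(pool, n_families, n_children) {
  lapply(seq_len(n_families), function(f) {
    fa <- sample.int(nrow(pool), 2, replace = TRUE, prob = pool$freq)
    mo <- sample.int(nrow(pool), 2, replace = TRUE, prob = pool$freq)
    kids <- lapply(seq_len(n_children), function(k) {
      c(fa[sample.int(2, 1)], mo[sample.int(2, 1)])
    })
    list(father = fa, mother = mo, children = kids)
  })
}

.families_to_cohort <- function(pool, draws) {
  pa <- .pool_alleles(pool)
  rownames(pa) <- pool$haplotype
  ids <- character(); grp <- character(); fam <- character()
  h1 <- integer(); h2 <- integer()
  ped <- list()
  for (f in seq_along(draws)) {
    d <- draws[[f]]
    fam_id <- sprintf("FAM%03d", f)
    fid <- sprintf("%s_F", fam_id); mid <- sprintf("%s_M", fam_id)
    ids <- c(ids, fid, mid); grp <- c(grp, "FDR", "FDR")
    fam <- c(fam, fam_id, fam_id)
    h1 <- c(h1, d$father[1], d$mother[1]); h2 <- c(h2, d$father[2], d$mother[2])
    ped[[length(ped) + 1]] <- data.frame(
      family_id = fam_id, subject_id = c(fid, mid),
      father_id = NA_character_, mother_id = NA_character_,
      sex = c("1", "2"), affected = FALSE, stringsAsFactors = FALSE)
    for (k in seq_along(d$children)) {
      cid <- sprintf("%s_C%d", fam_id, k)
      ids <- c(ids, cid); fam <- c(fam, fam_id)
      grp <- c(grp, if (k == 1) "NT1" else "FDR")
      h1 <- c(h1, d$children[[k]][1]); h2 <- c(h2, d$children[[k]][2])
      ped[[length(ped) + 1]] <- data.frame(
        family_id = fam_id, subject_id = cid, father_id = fid,
        mother_id = mid, sex = "0", affected = k == 1,
        stringsAsFactors = FALSE)
    }
  }
  subjects <- data.frame(subject_id = ids, group = grp, family_id = fam,
                         stringsAsFactors = FALSE)
  pedigree <- do.call(rbind, ped)
  class(pedigree) <- c("hla_pedigree", "data.frame")
  list(genotypes = .genotypes_from_pairs(subjects, pool$haplotype[h1],
                                         pool$haplotype[h2], pa),
       pedigree = pedigree,
       truth = .truth_df(ids, pool$haplotype[h1], pool$haplotype[h2]))
}

#' Ascertain unrelated cases under a risk model
#'
#' Rejection sampling: genotypes are drawn from the population distribution
#' and accepted with probability proportional to their genotype risk until
#' `n_cases` are accepted. With all risks equal this reduces to population
#' sampling; with an elevated anchor relative risk the case cohort is
#' enriched for anchor carriers.
#'
#' @param pool a [haplotype_pool()].
#' @param model a [risk_model()].
#' @param n_cases number of cases to accept.
#' @param seed optional integer seed.
#' @param group group label (default `"NT1"`); cases are emitted without
#'   family ids (unrelated design).
#' @return list: `genotypes`, `truth`.
#' @export
ascertain_cases <- function(pool, model, n_cases, seed = NULL,
                            group = "NT1") {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "risk_model"),
            n_cases > 0)
  if (!is.null(seed)) set.seed(seed)
  max_risk <- .max_genotype_risk(pool, model)
  if (max_risk <= 0) stop("risk model accepts no genotype", call. = FALSE)
  acc1 <- integer(); acc2 <- integer()
  while (length(acc1) < n_cases) {
    m <- max(2L * n_cases, 100L)
    i1 <- sample.int(nrow(pool), m, replace = TRUE, prob = pool$freq)
    i2 <- sample.int(nrow(pool), m, replace = TRUE, prob = pool$freq)
    r <- genotype_risk(model, pool$haplotype[i1], pool$haplotype[i2])
    keep <- stats::runif(m) < r / max_risk
    acc1 <- c(acc1, i1[keep]); acc2 <- c(acc2, i2[keep])
  }
  acc1 <- acc1[seq_len(n_cases)]; acc2 <- acc2[seq_len(n_cases)]
  ids <- sprintf("%s%04d", group, seq_len(n_cases))
  pa <- .pool_alleles(pool)
  rownames(pa) <- pool$haplotype
  # unrelated cases: GP-style subjects relabelled would trip the family-id
  # invariant, so each case is its own single-member family
  subjects <- data.frame(subject_id = ids, group = group,
                         family_id = if (group %in% c("NT1", "FDR"))
                           paste0("F_", ids) else NA_character_,
                         stringsAsFactors = FALSE)
  list(genotypes = .genotypes_from_pairs(subjects, pool$haplotype[acc1],
                                         pool$haplotype[acc2], pa),
       truth = .truth_df(ids, pool$haplotype[acc1], pool$haplotype[acc2]))
}

.max_genotype_risk <- function(pool, model) {
  h <- pool$haplotype
  grid <- expand.grid(i = seq_along(h), j = seq_along(h))
  max(genotype_risk(model, h[grid$i], h[grid$j]))
}

#' Simulate a full family-based case-control study
#'
#' Nuclear families with a risk-ascertained affected proband (family
#' genotypes are re-drawn until the proband's genotype is accepted under
#' the risk model, so proband genotypes follow the case distribution while
#' relatives are simply carriers of the transmitted haplotypes), plus an
#' unrelated general-population control cohort. First-degree relatives are
#' unaffected family members regardless of genotype (comparison group, not
#' a screened-negative group).
#'
#' @param pool a [haplotype_pool()].
#' @param model a [risk_model()].
#' @param n_families number of case families.
#' @param n_children children per family (first child = proband).
#' @param n_gp number of unrelated controls.
#' @param seed optional integer seed.
#' @return list: `genotypes` (NT1 + FDR + GP), `pedigree`, `truth`.
#' @export
simulate_study <- function(pool, model, n_families = 31, n_children = 1,
                           n_gp = 636, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "risk_model"))
  if (!is.null(seed)) set.seed(seed)
  max_risk <- .max_genotype_risk(pool, model)
  draws <- vector("list", n_families)
  got <- 0L
  while (got < n_families) {
    d <- .draw_families(pool, 1, n_children)[[1]]
    pro <- d$children[[1]]
    r <- genotype_risk(model, pool$haplotype[pro[1]], pool$haplotype[pro[2]])
    if (stats::runif(1) < r / max_risk) {
      got <- got + 1L
      draws[[got]] <- d
    }
  }
  famc <- .families_to_cohort(pool, draws)
  gp <- sample_population(pool, n_gp, group = "GP")
  subjects <- rbind(famc$genotypes$subjects, gp$genotypes$subjects)
  geno <- lapply(names(famc$genotypes$geno), function(s) {
    rbind(famc$genotypes$geno[[s]], gp$genotypes$geno[[s]])
  })
  names(geno) <- names(famc$genotypes$geno)
  list(genotypes = hla_genotypes(subjects, geno),
       pedigree = famc$pedigree,
       truth = rbind(famc$truth, gp$truth))
}
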