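test_that("fully homozygous subjects are phased trivially", {
  g <- toy_genotypes(list(
    DRB345 = list(rep("DRB5*01:01:01", 2)),
    DRB1 = list(rep("DRB1*15:01:01", 2)),
    DQA1 = list(rep("DQA1*01:02:01", 2)),
    DQB1 = list(rep("DQB1*06:02:01", 2))
  ))
  res <- assemble_by_anchor(g, test_anchor())
  expect_equal(res$phased$provenance, "homozygote")
  expect_equal(res$phased$hap1, res$phased$hap2)
  expect_equal(res$phased$hap1, test_anchor())
})

test_that("anchor heterozygotes are phased by subtraction", {
  # the worked published genotype: DR15 anchor on one chromosome, the
  # DRB4-DR4-DQ8-era haplotype on the other
  g <- toy_genotypes(list(
    DRB345 = list(c("DRB5*01:01:01", "DRB4*01:03:01")),
    DRB1 = list(c("DRB1*15:01:01", "DRB1*04:01:01")),
    DQA1 = list(c("DQA1*01:02:01", "DQA1*03:02//03:03:01")),
    DQB1 = list(c("DQB1*06:02:01", "DQB1*03:01:01"))
  ))
  res <- assemble_by_anchor(g, test_anchor())
  ph <- res$phased
  expect_equal(ph$provenance, "anchor_subtraction")
  second <- setdiff(c(ph$hap1, ph$hap2), test_anchor())
  expect_equal(second,
               paste0("DRB4*01:03:01-DRB1*04:01:01-",
                      "DQA1*03:02//03:03:01-DQB1*03:01:01"))
  expect_true(second %in% res$known$haplotype)
})

test_that("step 3 grows the known set to a fixed point", {
  # subject 1: anchor carrier seeds haplotype B; subject 2 decomposes as
  # B + C only after B is known; subject 3 has no decomposition
  A <- split_haplotype(test_anchor())
  B <- c("DRB4*01:03:01", "DRB1*04:01:01", "DQA1*03:02//03:03:01",
         "DQB1*03:01:01")
  C <- c("DRB3*01:01:02", "DRB1*03:01:01", "DQA1*05:01:01", "DQB1*02:01:01")
  D <- c("DRBX*null", "DRB1*01:01:01", "DQA1*01:01:01", "DQB1*05:01:01")
  E <- c("DRB3*02:02:01", "DRB1*11:01:01", "DQA1*05:05:01", "DQB1*03:01:01")
  slots <- extended_slots()
  g <- toy_genotypes(stats::setNames(lapply(seq_along(slots), function(j) {
    list(sort(c(A[j], B[j])), sort(c(B[j], C[j])), sort(c(D[j], E[j])))
  }), slots))
  res <- assemble_by_anchor(g, test_anchor())
  ph <- res$phased
  expect_equal(ph$provenance, c("anchor_subtraction", "known_match",
                                "unresolved"))
  expect_equal(sort(c(ph$hap1[2], ph$hap2[2])),
               sort(c(paste(B, collapse = "-"), paste(C, collapse = "-"))))
  expect_true(is.na(ph$hap1[3]))
  # unresolved subjects keep their admissible-split count
  expect_equal(ph$ambiguity_count[3], 2^3)
})

test_that("the DRB345 conflict rule assigns the shared allele to the more common haplotype", {
  # knowns H (with DRB4) and K (with DRB4) both match the subject's DRB4
  # allele; the subject's DRBX*null matches neither.  K is the more common,
  # so K keeps DRB4 and the remainder gets the null.
  H <- c("DRB4*01:03:01", "DRB1*04:01:01", "DQA1*03:01:01", "DQB1*03:02:01")
  K <- c("DRB4*01:03:01", "DRB1*07:01:01", "DQA1*02:01//02:01:01",
         "DQB1*02:02:01")
  slots <- extended_slots()
  homs <- function(h, times) lapply(seq_len(times), function(i) h)
  pairs <- stats::setNames(lapply(seq_along(slots), function(j) {
    c(homs(rep(H[j], 2), 1),       # 1 homozygote seeds H (2 copies)
      homs(rep(K[j], 2), 3),       # 3 homozygotes seed K (6 copies)
      list(sort(c(H[j], ifelse(j == 1, "DRBX*null", K[j])))))
  }), slots)
  g <- toy_genotypes(pairs)
  res <- assemble_by_anchor(g, test_anchor())
  row <- res$phased[5, ]
  expect_equal(row$provenance, "conflict_rule")
  expect_equal(row$ambiguity_count, 1)
  haps <- c(row$hap1, row$hap2)
  expect_true(paste(K, collapse = "-") %in% haps)  # common hap keeps DRB4
  null_hap <- setdiff(haps, paste(K, collapse = "-"))
  expect_equal(split_haplotype(null_hap)[1], "DRBX*null")
  expect_equal(split_haplotype(null_hap)[-1], unname(H[-1]))
})

test_that("allele multisets are conserved through anchor assembly", {
  pop <- sample_population(default_pool(), 120, seed = 5)
  res <- assemble_by_anchor(pop$genotypes, test_anchor())
  ph <- res$phased
  ok <- ph$provenance != "unresolved"
  for (s in names(pop$genotypes$geno)) {
    j <- match(s, hap_slots(ph$hap1[ok][1]))
    for (i in which(ok)) {
      got <- sort(c(split_haplotype(ph$hap1[i])[j],
                    split_haplotype(ph$hap2[i])[j]))
      expect_identical(got, unname(sort(pop$genotypes$geno[[s]][i, ])))
    }
  }
})

test_that("anchor assembly matches exhaustive decomposition on small cohorts", {
  # oracle: a subject's phase is uniquely determined when exactly one of
  # its 2^(h-1) splits consists of two generating-pool haplotypes
  pool <- default_pool()
  set.seed(31)
  for (rep in 1:6) {
    pop <- sample_population(pool, 12)
    res <- assemble_by_anchor(pop$genotypes, test_anchor())
    ph <- res$phased
    slots <- names(pop$genotypes$geno)
    for (i in seq_len(12)) {
      gm <- do.call(rbind, lapply(slots, function(s) pop$genotypes$geno[[s]][i, ]))
      L <- nrow(gm)
      combos <- as.matrix(expand.grid(rep(list(1:2), L)))
      pairs <- unique(apply(combos, 1, function(k) {
        h1 <- paste(gm[cbind(1:L, k)], collapse = "-")
        h2 <- paste(gm[cbind(1:L, 3 - k)], collapse = "-")
        paste(sort(c(h1, h2)), collapse = "|")
      }))
      in_pool <- vapply(pairs, function(p) {
        all(strsplit(p, "|", fixed = TRUE)[[1]] %in% pool$haplotype)
      }, logical(1))
      if (sum(in_pool) == 1 && ph$provenance[i] != "unresolved") {
        expect_equal(pair_key(ph$hap1[i], ph$hap2[i]), pairs[in_pool])
      }
    }
  }
})

test_that("phase accuracy degrades as pool LD structure weakens", {
  # pool A: four haplotypes, alleles unique to each (maximal LD);
  # pool B: same allele sets recombined crosswise (every recombinant is a
  # real haplotype, so decompositions are maximally ambiguous)
  mk <- function(rows) {
    haplotype_pool(vapply(rows, function(r) {
      hap_label(c(paste0("DRB1*", r[1]), paste0("DQA1*", r[2]),
                  paste0("DQB1*", r[3])))
    }, ""), rep(0.25, 4))
  }
  poolA <- mk(list(c("01:01", "01:01", "05:01"), c("03:01", "05:01", "02:01"),
                   c("15:01", "01:02", "06:02"), c("04:01", "03:01", "03:02")))
  poolB <- mk(list(c("01:01", "01:01", "05:01"), c("03:01", "05:01", "02:01"),
                   c("01:01", "05:01", "05:01"), c("03:01", "01:01", "02:01")))
  anchor_of <- function(pool) pool$haplotype[3]
  rate <- function(pool, seed) {
    pop <- sample_population(pool, 150, seed = seed)
    res <- assemble_by_anchor(pop$genotypes, anchor_of(pool),
                              slots = c("DRB1", "DQA1", "DQB1"))
    ph <- res$phased
    ok <- ph$provenance != "unresolved"
    mean(pair_key(ph$hap1[ok], ph$hap2[ok]) ==
           pair_key(pop$truth$true_hap1[ok], pop$truth$true_hap2[ok]))
  }
  expect_gte(rate(poolA, 8), rate(poolB, 8))
})

test_that("assembly recovers generating pairs for nearly all subjects", {
  pop <- sample_population(default_pool(), 200, seed = 60)
  res <- assemble_by_anchor(pop$genotypes, test_anchor())
  ph <- res$phased
  ok <- ph$provenance != "unresolved"
  acc <- mean(pair_key(ph$hap1[ok], ph$hap2[ok]) ==
                pair_key(pop$truth$true_hap1[ok], pop$truth$true_hap2[ok]))
  expect_gte(acc, 0.95)
})
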