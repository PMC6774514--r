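# small helper: build family genotypes + pedigree from haplotype indices
# into a pool, with the generating truth
family_fixture <- function(pool, father, mother, kids) {
  labs <- pool$haplotype
  split_h <- function(i) strsplit(labs[i], "-", fixed = TRUE)[[1]]
  slots <- hap_slots(labs[1])
  members <- c(list(father, mother), kids)
  ids <- c("dad", "mom", sprintf("kid%d", seq_along(kids)))
  pairs <- lapply(seq_along(slots), function(j) {
    lapply(members, function(m) {
      sort(c(split_h(m[1])[j], split_h(m[2])[j]))
    })
  })
  names(pairs) <- slots
  subjects <- data.frame(subject_id = ids,
                         group = c("FDR", "FDR", "NT1",
                                   rep("FDR", length(kids) - 1))[seq_along(ids)],
                         family_id = "F1", stringsAsFactors = FALSE)
  g <- hla_genotypes(subjects, lapply(pairs, function(p) do.call(rbind, p)))
  ped <- data.frame(
    family_id = "F1", subject_id = ids,
    father_id = c(NA, NA, rep("dad", length(kids))),
    mother_id = c(NA, NA, rep("mom", length(kids))),
    sex = "0", affected = c(FALSE, FALSE, TRUE,
                            rep(FALSE, length(kids) - 1))[seq_along(ids)],
    stringsAsFactors = FALSE)
  truth <- lapply(members, function(m) sort(labs[m]))
  list(genotypes = g, pedigree = ped, truth = truth, ids = ids)
}

test_that("a trio with fully homozygous parents is forced", {
  pool <- default_pool()
  fix <- family_fixture(pool, father = c(1, 1), mother = c(5, 5),
                        kids = list(c(1, 5)))
  ph <- phase_by_descent(fix$pedigree, fix$genotypes)
  expect_true(all(ph$provenance == "descent"))
  expect_true(all(ph$ambiguity_count == 1))
  kid <- ph[ph$subject_id == "kid1", ]
  expect_equal(sort(c(kid$hap1, kid$hap2)), fix$truth[[3]])
})

test_that("heterozygous trios are resolved by elimination", {
  pool <- default_pool()
  fix <- family_fixture(pool, father = c(1, 2), mother = c(5, 6),
                        kids = list(c(2, 5)))
  ph <- phase_by_descent(fix$pedigree, fix$genotypes)
  for (i in seq_along(fix$ids)) {
    row <- ph[ph$subject_id == fix$ids[i], ]
    expect_equal(row$provenance, "descent")
    expect_equal(sort(c(row$hap1, row$hap2)), fix$truth[[i]])
  }
})

test_that("symmetric identically-heterozygous families stay unresolved", {
  pool <- default_pool()
  # both parents carry the same two haplotypes, the child too: the two
  # phase assignments are indistinguishable
  fix <- family_fixture(pool, father = c(1, 5), mother = c(1, 5),
                        kids = list(c(1, 5)))
  ph <- phase_by_descent(fix$pedigree, fix$genotypes)
  kid <- ph[ph$subject_id == "kid1", ]
  expect_equal(kid$provenance, "unresolved")
  expect_gt(kid$ambiguity_count, 1)
})

test_that("Mendelian inconsistencies are reported with family, subject, locus", {
  pool <- default_pool()
  fix <- family_fixture(pool, father = c(1, 1), mother = c(5, 5),
                        kids = list(c(6, 7)))  # child unrelated to parents
  expect_error(phase_by_descent(fix$pedigree, fix$genotypes),
               "Mendelian inconsistency in family F1, subject kid1, locus")
})

test_that("descent phasing agrees with brute-force enumeration on random families", {
  pool <- default_pool()
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:25) {
    father <- sample.int(16, 2, replace = TRUE, prob = pool$freq)
    mother <- sample.int(16, 2, replace = TRUE, prob = pool$freq)
    n_kids <- sample(1:2, 1)
    kids <- lapply(seq_len(n_kids), function(k) {
      c(sample(father, 1), sample(mother, 1))
    })
    fix <- family_fixture(pool, father, mother, kids)
    ph <- phase_by_descent(fix$pedigree, fix$genotypes)

    slots <- names(fix$genotypes$geno)
    gmat <- function(id) {
      i <- match(id, fix$genotypes$subjects$subject_id)
      do.call(rbind, lapply(slots, function(s) fix$genotypes$geno[[s]][i, ]))
    }
    oracle <- brute_family_phase(gmat("dad"), gmat("mom"),
                                 lapply(seq_len(n_kids),
                                        function(k) gmat(sprintf("kid%d", k))))
    for (i in seq_along(fix$ids)) {
      row <- ph[ph$subject_id == fix$ids[i], ]
      expect_equal(row$ambiguity_count, length(oracle[[i]]))
      if (length(oracle[[i]]) == 1) {
        expect_equal(paste(row$hap1, row$hap2, sep = "|"), oracle[[i]])
        n_checked <- n_checked + 1
      }
      # allele conservation at every locus
      if (!is.na(row$hap1)) {
        for (j in seq_along(slots)) {
          got <- sort(c(split_haplotype(row$hap1)[j], split_haplotype(row$hap2)[j]))
          expect_equal(got, unname(sort(fix$genotypes$geno[[slots[j]]][i, ])))
        }
      }
    }
  }
  expect_gt(n_checked, 20)  # the comparison actually exercised resolved cases
})

test_that("phased children never carry haplotypes absent from phased parents", {
  pool <- default_pool()
  fams <- sample_families(pool, 30, n_children = 2, seed = 99)
  ph <- phase_families(fams$genotypes, fams$pedigree)
  ped <- fams$pedigree
  for (i in which(!is.na(ped$father_id))) {
    kid <- ph[ph$subject_id == ped$subject_id[i], ]
    dad <- ph[ph$subject_id == ped$father_id[i], ]
    mom <- ph[ph$subject_id == ped$mother_id[i], ]
    if (kid$provenance != "descent" || dad$provenance != "descent" ||
        mom$provenance != "descent") next
    parental <- c(dad$hap1, dad$hap2, mom$hap1, mom$hap2)
    expect_true(all(c(kid$hap1, kid$hap2) %in% parental))
  }
})

test_that("descent phasing recovers the generating phase of simulated trios", {
  pool <- default_pool()
  fams <- sample_families(pool, 40, n_children = 1, seed = 7)
  ph <- phase_families(fams$genotypes, fams$pedigree)
  m <- match(ph$subject_id, fams$truth$subject_id)
  resolved <- ph$provenance == "descent"
  expect_gt(sum(resolved), 60)
  expect_true(all(pair_key(ph$hap1[resolved], ph$hap2[resolved]) ==
                    pair_key(fams$truth$true_hap1[m][resolved],
                             fams$truth$true_hap2[m][resolved])))
})
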