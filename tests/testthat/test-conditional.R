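# phased cohort fixture with known carrier structure
phased_fixture <- function() {
  anchor <- test_anchor()
  B <- paste0("DRB4*01:03:01-DRB1*04:01:01-DQA1*03:02//03:03:01-",
              "DQB1*03:01:01")
  C <- "DRB3*01:01:02-DRB1*03:01:01-DQA1*05:01:01-DQB1*02:01:01"
  data.frame(
    subject_id = sprintf("s%02d", 1:10),
    group = c(rep("NT1", 5), rep("GP", 5)),
    hap1 = c(anchor, anchor, anchor, C, anchor, anchor, anchor, C, C, anchor),
    hap2 = c(anchor, B, C, C, NA, B, C, C, B, anchor),
    provenance = c(rep("known_match", 4), "unresolved",
                   rep("known_match", 5)),
    ambiguity_count = 1, stringsAsFactors = FALSE)
}

test_that("carrier selection partitions homozygotes, heterozygotes, seconds", {
  ph <- phased_fixture()
  cs <- select_carriers(ph, test_anchor(), "NT1")
  expect_equal(length(cs$carriers), 3)
  expect_equal(cs$homozygotes, "s01")
  expect_setequal(cs$heterozygotes, c("s02", "s03"))
  expect_setequal(cs$second_haplotypes,
                  c(paste0("DRB4*01:03:01-DRB1*04:01:01-",
                           "DQA1*03:02//03:03:01-DQB1*03:01:01"),
                    "DRB3*01:01:02-DRB1*03:01:01-DQA1*05:01:01-DQB1*02:01:01"))
  expect_equal(cs$n_unresolved, 1)
  # sizes are consistent
  expect_equal(length(cs$homozygotes) + length(cs$heterozygotes),
               length(cs$carriers))
  expect_equal(length(cs$second_haplotypes), length(cs$heterozygotes))
})

test_that("anchor matching works across field resolutions", {
  ph <- phased_fixture()
  two_field <- "DRB5*01:01-DRB1*15:01-DQA1*01:02-DQB1*06:02"
  cs3 <- select_carriers(ph, test_anchor(), "GP", resolution = 3)
  cs2 <- select_carriers(ph, two_field, "GP", resolution = 2)
  expect_equal(sort(cs3$carriers), sort(cs2$carriers))
  # a cohort with no carriers yields an empty set
  none <- select_carriers(ph[ph$hap1 == ph$hap2[4], ], test_anchor(), "NT1")
  expect_length(none$carriers, 0)
})

test_that("second-haplotype rows conserve the heterozygote multiset", {
  ph <- phased_fixture()
  cs_case <- select_carriers(ph, test_anchor(), "NT1")
  cs_ctrl <- select_carriers(ph, test_anchor(), "GP")
  tab <- second_haplotype_association(cs_case, cs_ctrl)
  expect_equal(sum(tab$case_n), length(cs_case$heterozygotes))
  expect_equal(sum(tab$control_n), length(cs_ctrl$heterozygotes))
  expect_true(all(c("case_het_total", "case_carrier_total") %in% names(tab)))
})

test_that("published carrier counts flag the DRB4 second haplotype, not homozygosity", {
  cond <- nt1_reference_counts("conditional_gp")
  carriers <- cond[cond$quantity == "anchor_carriers", ]
  homs <- cond[cond$quantity == "anchor_homozygotes", ]
  second <- cond[grepl("^second_", cond$quantity), ]
  het_case <- carriers$case_n - homs$case_n       # 26
  het_ctrl <- carriers$control_n - homs$control_n # 162
  r_second <- assoc_2x2(second$case_n, het_case - second$case_n,
                        second$control_n, het_ctrl - second$control_n)
  expect_lt(r_second$p, 0.05)
  expect_gt(r_second$or, 1)
  r_hom <- assoc_2x2(homs$case_n, het_case, homs$control_n, het_ctrl)
  expect_gt(r_hom$p, 0.05)
})

test_that("identical homozygosity rates give OR 1; synthetic nulls stay null", {
  mk_set <- function(group, n_hom, n_het, second) {
    structure(list(group = group,
                   carriers = sprintf("%s%03d", group, seq_len(n_hom + n_het)),
                   homozygotes = sprintf("%s%03d", group, seq_len(n_hom)),
                   heterozygotes = sprintf("%s%03d", group,
                                           n_hom + seq_len(n_het)),
                   second_haplotypes = second, n_unresolved = 0L),
              class = "carrier_set")
  }
  a <- mk_set("NT1", 4, 16, rep(c("X", "Y"), c(8, 8)))
  b <- mk_set("GP", 8, 32, rep(c("X", "Y"), c(16, 16)))
  expect_equal(homozygosity_test(a, b)$or, 1)
  tab <- second_haplotype_association(a, b)
  expect_true(all(tab$or == 1))
  expect_true(all(tab$p > 0.9))
})

test_that("carrier counts agree with carrier-unit frequency tables", {
  pop <- sample_population(default_pool(), 250, seed = 17)
  res <- assemble_by_anchor(pop$genotypes, test_anchor())
  ph <- res$phased
  ph$group <- "GP"
  cs <- select_carriers(ph, test_anchor(), "GP")
  ok <- ph$provenance != "unresolved"
  x <- data.frame(subject_id = rep(ph$subject_id[ok], 2), group = "GP",
                  category = c(ph$hap1[ok], ph$hap2[ok]))
  freq <- build_frequency_table(x, unit = "carriers")
  expect_equal(unname(freq$counts[test_anchor(), "GP"]),
               length(cs$carriers))
})

test_that("homozygote enrichment is recovered within the Woolf interval", {
  # generator: carriers homozygous with probability q_case vs q_ctrl such
  # that the generating odds ratio is 3; at n = 500 per group the Woolf CI
  # should cover 3 in >= 90% of replicates
  q_ctrl <- 0.2
  or_true <- 3
  q_case <- or_true * 0.25 / (1 + or_true * 0.25)  # odds 0.25 -> OR 3
  set.seed(505)
  cover <- replicate(200, {
    a <- rbinom(1, 500, q_case)
    c_ <- rbinom(1, 500, q_ctrl)
    ci <- woolf_ci(a, 500 - a, c_, 500 - c_)
    ci[1] <= or_true && or_true <= ci[2]
  })
  expect_gte(mean(cover), 0.9)
})
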