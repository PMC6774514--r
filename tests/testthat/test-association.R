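test_that("cross-product OR reproduces published values and symmetries", {
  expect_equal(round(cross_product_or(34, 28, 205, 1067), 2), 6.32)
  expect_equal(round(cross_product_or(38, 24, 55, 77), 2), 2.22)
  for (k in c(1, 3, 10)) expect_equal(cross_product_or(k, k, k, k), 1)
  # group-swap inversion
  expect_equal(cross_product_or(7, 11, 5, 13) * cross_product_or(5, 13, 7, 11), 1)
  # undefined when a denominator cell is zero
  expect_true(is.na(cross_product_or(3, 0, 5, 2)))
  expect_error(cross_product_or(-1, 2, 3, 4), "non-negative")
})

test_that("Woolf intervals reproduce published bounds and scale correctly", {
  expect_equal(round(unname(woolf_ci(34, 28, 205, 1067)), 2), c(3.75, 10.65))
  expect_equal(round(unname(woolf_ci(38, 24, 265, 1007)), 2), c(3.55, 10.21))
  # symmetric table: bounds multiplicatively symmetric about 1
  ci <- woolf_ci(10, 20, 10, 20)
  expect_equal(unname(ci[1] * ci[2]), 1)
  # width (on the log scale) non-increasing as all cells scale up
  widths <- sapply(1:4, function(k) {
    ci <- woolf_ci(5 * k, 7 * k, 6 * k, 9 * k)
    log(ci[2]) - log(ci[1])
  })
  expect_true(all(diff(widths) <= 0))
  expect_true(all(is.na(woolf_ci(0, 5, 5, 5))))
})

test_that("Pearson chi-square (no continuity correction) matches printed p-values", {
  expect_equal(signif(pearson_chi2_p(34, 28, 205, 1067), 3), 8.24e-15)
  expect_equal(signif(pearson_chi2_p(38, 24, 55, 77), 3), 1.07e-2)
  # a table equal to its expected counts has chi-square 0, p = 1
  expect_equal(pearson_chi2_p(10, 30, 20, 60), 1)
  # invariance under simultaneous row and column swaps
  expect_equal(pearson_chi2_p(7, 13, 4, 29), pearson_chi2_p(29, 4, 13, 7))
})

test_that("Fisher exact p matches enumeration and hand-derived cases", {
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_p(5, 0, 0, 5), 2 / 252)
  expect_equal(signif(fisher_exact_p(3, 59, 6, 1266), 3), 6.58e-3)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration for N <= 30", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    p_pkg <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    p_enum <- enum_fisher_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_pkg, p_enum, tolerance = 1e-10)
  }
})

test_that("test selection uses the expected-cell-below-5 Fisher fallback", {
  expect_equal(choose_test(34, 28, 205, 1067), "chi2")
  expect_equal(choose_test(3, 59, 6, 1266), "fisher")   # expected a ~ 0.42
  expect_equal(choose_test(0, 10, 0, 10), "fisher")
  expect_equal(choose_test(3, 59, 6, 1266, rule = "chi2"), "chi2")
  expect_equal(min(expected_cells(34, 28, 205, 1067)), 62 * 239 / 1334)
})

test_that("conditional-MLE estimator reproduces the small-cell published OR", {
  expect_equal(round(conditional_or(5, 26, 6, 630), 2), 19.89)
  r <- assoc_2x2(5, 26, 6, 630, estimator = "conditional")
  expect_equal(round(r$or, 2), 19.89)
})

test_that("frequency tables count haplotype slots and carriers as published", {
  anchor <- test_anchor()
  other <- "DRBX*null-DRB1*01:01:01-DQA1*01:01:01-DQB1*05:01:01"
  # 31 subjects: 4 anchor homozygotes, 26 heterozygotes, 1 non-carrier
  h1 <- c(rep(anchor, 30), other)
  h2 <- c(rep(anchor, 4), rep(other, 27))
  x <- data.frame(subject_id = rep(sprintf("P%02d", 1:31), 2),
                  group = "NT1", category = c(h1, h2))
  slots <- build_frequency_table(x, unit = "haplotype_slots")
  expect_equal(unname(slots$denom["NT1"]), 62)
  expect_equal(unname(slots$counts[anchor, "NT1"]), 34)
  expect_equal(round(slots$pct[anchor, "NT1"], 1), 54.8)
  carriers <- build_frequency_table(x, unit = "carriers")
  expect_equal(unname(carriers$denom["NT1"]), 31)
  expect_equal(unname(carriers$counts[anchor, "NT1"]), 30)
  expect_equal(round(carriers$pct[anchor, "NT1"], 1), 96.8)
})

test_that("category-vs-rest tables reproduce the published cells", {
  t1 <- nt1_reference_counts("alleles_gp")
  freq <- freq_from_counts(t1[t1$block == "DRB345", ], 62, 1272)
  tab <- category_vs_rest(freq, "DRB5*01:01:01", "NT1", "GP")
  expect_equal(unname(tab), c(34, 28, 205, 1067))
  expect_error(category_vs_rest(freq, "DQB1*06:02:01", "NT1", "GP"), "absent")
  # all-identical cohort: one category at 100%
  x <- data.frame(subject_id = rep(1:5, 2), group = "GP", category = "A")
  f1 <- build_frequency_table(x, "haplotype_slots")
  expect_equal(unname(f1$pct["A", "GP"]), 100)
})

test_that("rare partition is inclusive at the threshold and exhaustive", {
  counts <- data.frame(category = c("x", "y", "z"),
                       case_n = c(1, 0, 0), control_n = c(1, 12, 612))
  f <- freq_from_counts(counts, 62, 1272, other_label = NULL)
  part <- rare_partition(f, threshold = 1)
  expect_setequal(part$common, c("x", "z"))   # x: 1.6% in cases; z: 48%
  expect_setequal(part$rare, "y")             # 12/1272 = 0.94% in both
  # boundary: exactly the threshold is common
  f2 <- freq_from_counts(data.frame(category = "w", case_n = 0, control_n = 10),
                         100, 1000)
  expect_true("w" %in% rare_partition(f2, 1)$common)
  expect_equal(sort(c(part$common, part$rare)), sort(rownames(f$counts)))
})
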