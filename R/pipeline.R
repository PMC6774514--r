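#' Pipeline configuration
#'
#' Defaults encode the reference analysis: extended haplotypes over
#' DRB345-DRB1-DQA1-DQB1, the DR15 anchor haplotype, the two DQA1 merge
#' groups, a 1% common/rare threshold, RPE with alpha 0.05 and a minimum
#' case count of 2, cross-product odds ratios with Woolf intervals, and
#' expected-cell-below-5 Fisher fallback.
#'
#' @param slots locus slots analysed at allele level.
#' @param extended_slots slots of the extended haplotype.
#' @param anchor anchor haplotype label.
#' @param merge_rules list of [merge_rule()].
#' @param rare_threshold common/rare percent threshold in (0, 100).
#' @param alpha RPE significance threshold.
#' @param min_case_count RPE minimal case count for exclusion.
#' @param estimator `"cross"` or `"conditional"` odds-ratio estimator.
#' @param test_rule 2x2 test-selection rule (see [choose_test()]).
#' @param resolution anchor-matching field resolution.
#' @param level confidence level.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(slots = hla_slots(),
                            extended_slots = c("DRB345", "DRB1", "DQA1", "DQB1"),
                            anchor = paste0("DRB5*01:01:01-DRB1*15:01:01-",
                                            "DQA1*01:02:01-DQB1*06:02:01"),
                            merge_rules = default_merge_rules(),
                            rare_threshold = 1, alpha = 0.05,
                            min_case_count = 2, estimator = "cross",
                            test_rule = "expected5", resolution = 3,
                            level = 0.95) {
  stopifnot(all(extended_slots %in% slots), all(slots %in% hla_slots()),
            rare_threshold > 0, rare_threshold < 100,
            alpha > 0, alpha < 1)
  validate_merge_rules(merge_rules)
  if (!setequal(hap_slots(anchor), extended_slots)) {
    stop("anchor must cover exactly the extended slots", call. = FALSE)
  }
  structure(list(slots = slots, extended_slots = extended_slots,
                 anchor = anchor, merge_rules = merge_rules,
                 rare_threshold = rare_threshold, alpha = alpha,
                 min_case_count = min_case_count, estimator = estimator,
                 test_rule = test_rule, resolution = resolution,
                 level = level),
            class = "pipeline_config")
}

# long data.frame of allele slots at one locus (two rows per typed subject)
.allele_long <- function(genotypes, slot) {
  m <- genotypes$geno[[slot]]
  ok <- !is.na(m[, 1])
  data.frame(
    subject_id = rep(genotypes$subjects$subject_id[ok], 2),
    group = rep(genotypes$subjects$group[ok], 2),
    category = c(m[ok, 1], m[ok, 2]),
    stringsAsFactors = FALSE
  )
}

# long data.frame of haplotype slots projected onto a slot subset
.hap_long <- function(phased, subset) {
  ok <- phased$provenance != "unresolved" & !is.na(phased$hap1)
  x <- phased[ok, ]
  data.frame(
    subject_id = rep(x$subject_id, 2),
    group = rep(x$group, 2),
    category = haplotype_label(c(x$hap1, x$hap2), subset),
    stringsAsFactors = FALSE
  )
}

.compare_block <- function(freq, case_group, control_group, config) {
  if (!case_group %in% colnames(freq$counts) ||
      !control_group %in% colnames(freq$counts)) return(NULL)
  part <- rare_partition(freq, config$rare_threshold)
  assoc <- associate_all(freq, case_group, control_group,
                         categories = part$common,
                         estimator = config$estimator,
                         test_rule = config$test_rule, level = config$level)
  trace <- run_rpe(freq$counts[, case_group], freq$counts[, control_group],
                   alpha = config$alpha,
                   min_case_count = config$min_case_count,
                   test_rule = config$test_rule)
  list(association = assoc, rpe = trace, common = part$common,
       rare = part$rare, freq = freq)
}

#' Run the full analysis pipeline
#'
#' From a subject genotype table (and optionally a pedigree) to the full
#' result bundle, in chromosomal order: per-locus allele tables with
#' common/rare partitions, association statistics and RPE traces for NT1
#' vs GP and NT1 vs FDR; DR-block, DQ-block and extended-haplotype tables;
#' extended genotype tables; and the conditional analyses among anchor
#' carriers. Family members are phased by descent, everyone else by anchor
#' assembly seeded with the family haplotypes. Every emitted p-value is
#' recorded in a run log together with its 2x2 cells and the test used.
#'
#' @param genotypes an [hla_genotypes()].
#' @param pedigree optional [read_pedigree()] data.frame for the families.
#' @param config a [pipeline_config()].
#' @return list of class `hla_pipeline_result` with elements `phased`,
#'   `known`, `alleles` (per slot, per comparison), `haplotypes` (per
#'   block), `genotypes_block`, `conditional`, `log`, `config`.
#' @export
run_pipeline <- function(genotypes, pedigree = NULL,
                         config = pipeline_config()) {
  groups <- unique(genotypes$subjects$group)
  if (!"NT1" %in% groups || sum(genotypes$subjects$group == "NT1") == 0) {
    stop("case group NT1 is empty", call. = FALSE)
  }
  if (!any(c("GP", "FDR") %in% groups)) {
    stop("no control group (GP or FDR) present", call. = FALSE)
  }

  # --- phasing ------------------------------------------------------------
  fam_phased <- NULL
  known <- NULL
  if (!is.null(pedigree)) {
    sizes <- table(pedigree$family_id[pedigree$subject_id %in%
                                        genotypes$subjects$subject_id])
    multi <- names(sizes)[sizes >= 2]
    if (length(multi)) {
      fam_phased <- phase_families(genotypes,
                                   pedigree[pedigree$family_id %in% multi, ],
                                   slots = config$extended_slots)
      res <- fam_phased[fam_phased$provenance == "descent", ]
      haps <- c(res$hap1, res$hap2)
      if (length(haps)) {
        tab <- table(haps)
        known <- known_haplotypes(names(tab), as.integer(tab))
      }
    }
  }
  rest_ids <- setdiff(genotypes$subjects$subject_id,
                      if (is.null(fam_phased)) character()
                      else fam_phased$subject_id)
  phased <- NULL
  if (length(rest_ids)) {
    sub <- .subset_genotypes(genotypes, rest_ids)
    asm <- assemble_by_anchor(sub, config$anchor, known = known,
                              slots = config$extended_slots)
    phased <- asm$phased
    known <- asm$known
  }
  phased <- rbind(fam_phased, phased)
  phased$group <- genotypes$subjects$group[match(phased$subject_id,
                                                 genotypes$subjects$subject_id)]

  comparisons <- list(c("NT1", "GP"), c("NT1", "FDR"))
  comparisons <- Filter(function(x) x[2] %in% groups, comparisons)
  cmp_name <- function(x) paste(x, collapse = "_vs_")

  # --- allele level -------------------------------------------------------
  alleles <- list()
  for (s in intersect(config$slots, names(genotypes$geno))) {
    freq <- build_frequency_table(.allele_long(genotypes, s),
                                  unit = "haplotype_slots")
    alleles[[s]] <- lapply(stats::setNames(comparisons,
                                           vapply(comparisons, cmp_name, "")),
                           function(cg) .compare_block(freq, cg[1], cg[2],
                                                       config))
  }

  # --- haplotype level ----------------------------------------------------
  blocks <- list(dr_drb1 = c("DRB345", "DRB1"), dq = c("DQA1", "DQB1"),
                 extended = config$extended_slots)
  haplotypes <- lapply(blocks, function(subset) {
    freq <- build_frequency_table(.hap_long(phased, subset),
                                  unit = "haplotype_slots")
    lapply(stats::setNames(comparisons, vapply(comparisons, cmp_name, "")),
           function(cg) .compare_block(freq, cg[1], cg[2], config))
  })

  # --- genotype level -----------------------------------------------------
  ok <- phased$provenance != "unresolved" & !is.na(phased$hap1)
  gx <- data.frame(subject_id = phased$subject_id[ok],
                   group = phased$group[ok],
                   category = paste(phased$hap1[ok], phased$hap2[ok],
                                    sep = " / "),
                   stringsAsFactors = FALSE)
  gfreq <- build_frequency_table(gx, unit = "subjects")
  genotypes_block <- lapply(stats::setNames(comparisons,
                                            vapply(comparisons, cmp_name, "")),
                            function(cg) .compare_block(gfreq, cg[1], cg[2],
                                                        config))

  # --- conditional --------------------------------------------------------
  conditional <- NULL
  if ("GP" %in% groups) {
    cs_case <- select_carriers(phased, config$anchor, "NT1",
                               config$resolution)
    cs_ctrl <- select_carriers(phased, config$anchor, "GP",
                               config$resolution)
    if (length(cs_case$carriers) && length(cs_ctrl$carriers)) {
      conditional <- list(
        cases = cs_case, controls = cs_ctrl,
        second_haplotypes = second_haplotype_association(
          cs_case, cs_ctrl, estimator = config$estimator,
          test_rule = config$test_rule, level = config$level),
        homozygosity = homozygosity_test(
          cs_case, cs_ctrl, estimator = config$estimator,
          test_rule = config$test_rule, level = config$level)
      )
    }
  }

  res <- structure(list(phased = phased, known = known, alleles = alleles,
                        haplotypes = haplotypes,
                        genotypes_block = genotypes_block,
                        conditional = conditional, config = config),
                   class = "hla_pipeline_result")
  res$log <- .collect_log(res)
  res
}

.subset_genotypes <- function(genotypes, ids) {
  keep <- genotypes$subjects$subject_id %in% ids
  geno <- lapply(genotypes$geno, function(m) m[keep, , drop = FALSE])
  subj <- genotypes$subjects[keep, ]
  rownames(subj) <- NULL
  structure(list(subjects = subj, geno = geno), class = "hla_genotypes")
}

# audit log: every single-shot p-value with its cells and test
.collect_log <- function(res) {
  rows <- list()
  grab <- function(stage, block, cmp) {
    if (is.null(cmp) || is.null(cmp$association) ||
        nrow(cmp$association) == 0) return()
    a <- cmp$association
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, block = block, category = a$category, a = a$a, b = a$b,
      c = a$c, d = a$d, p = a$p, test_used = a$test_used,
      stringsAsFactors = FALSE)
  }
  for (s in names(res$alleles)) {
    for (cn in names(res$alleles[[s]])) grab("allele", paste(s, cn), res$alleles[[s]][[cn]])
  }
  for (b in names(res$haplotypes)) {
    for (cn in names(res$haplotypes[[b]])) grab("haplotype", paste(b, cn), res$haplotypes[[b]][[cn]])
  }
  for (cn in names(res$genotypes_block)) {
    grab("genotype", cn, res$genotypes_block[[cn]])
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' @export
print.hla_pipeline_result <- function(x, ...) {
  cat("<hla_pipeline_result>\n",
      "  phased subjects: ", nrow(x$phased), " (",
      sum(x$phased$provenance == "unresolved"), " unresolved)\n",
      "  allele slots: ", paste(names(x$alleles), collapse = ", "), "\n",
      "  haplotype blocks: ", paste(names(x$haplotypes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run association + RPE from published category counts
#'
#' Fixture mode: published tables give, per block (locus or haplotype
#' family), counts for selected categories and the group totals. The
#' unlisted remainder of each block is pooled into a background category
#' that completes the denominators but is never tested or excluded (see
#' [freq_from_counts()]). From the table-building step onward the
#' statistical path is identical to subject-level mode.
#'
#' @param counts data.frame with columns `category`, `case_n`,
#'   `control_n`, and optionally `block` (processed per block).
#' @param case_total,control_total group denominators (haplotype slots or
#'   subjects, as published).
#' @param case_label,control_label group names.
#' @param config a [pipeline_config()].
#' @return named list per block: `association`, `rpe`, `freq`.
#' @export
run_from_counts <- function(counts, case_total, control_total,
                            case_label = "NT1", control_label = "GP",
                            config = pipeline_config()) {
  if (any(counts$case_n > case_total) || any(counts$control_n > control_total)) {
    stop("counts exceed declared totals", call. = FALSE)
  }
  blocks <- if ("block" %in% names(counts)) split(counts, counts$block)
            else list(all = counts)
  lapply(blocks, function(b) {
    freq <- freq_from_counts(b, case_total, control_total,
                             case_label, control_label)
    bg <- setdiff(rownames(freq$counts), b$category)
    assoc <- associate_all(freq, case_label, control_label, exclude = bg,
                           estimator = config$estimator,
                           test_rule = config$test_rule,
                           level = config$level)
    trace <- run_rpe(freq$counts[, case_label], freq$counts[, control_label],
                     alpha = config$alpha,
                     min_case_count = config$min_case_count,
                     test_rule = config$test_rule,
                     background = if (length(bg)) bg else NULL)
    list(association = assoc, rpe = trace, freq = freq)
  })
}

#' Write the pipeline result bundle to a directory
#'
#' One CSV per table (association results with appended RPE round
#' columns), a per-subject phased haplotype TSV, and the audit log.
#' Re-running with identical inputs produces byte-identical files.
#'
#' @param res an `hla_pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(cmp, name) {
    if (is.null(cmp)) return()
    tab <- merge(cmp$association, as.data.frame(cmp$rpe)[
      c("category", grep("^p_round", names(as.data.frame(cmp$rpe)),
                         value = TRUE))],
      by = "category", all.x = TRUE, sort = FALSE)
    p <- file.path(dir, paste0(name, ".csv"))
    write_association_table(tab, p)
    paths <<- c(paths, p)
  }
  for (s in names(res$alleles)) {
    for (cn in names(res$alleles[[s]])) {
      emit(res$alleles[[s]][[cn]], paste0("alleles_", s, "_", cn))
    }
  }
  for (b in names(res$haplotypes)) {
    for (cn in names(res$haplotypes[[b]])) {
      emit(res$haplotypes[[b]][[cn]], paste0("haplotypes_", b, "_", cn))
    }
  }
  for (cn in names(res$genotypes_block)) {
    emit(res$genotypes_block[[cn]], paste0("genotypes_", cn))
  }
  if (!is.null(res$conditional)) {
    p <- file.path(dir, "conditional_second_haplotypes.csv")
    write_association_table(res$conditional$second_haplotypes, p)
    paths <- c(paths, p)
    p <- file.path(dir, "conditional_homozygosity.csv")
    write_association_table(res$conditional$homozygosity, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "phased_subjects.tsv")
  write_haplotype_table(res$phased, p)
  paths <- c(paths, p)
  if (!is.null(res$log)) {
    p <- file.path(dir, "run_log.csv")
    utils::write.csv(res$log, p, row.names = FALSE, quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
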