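---
title: "Methods: HLA class II case-control association with extended haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA class II case-control association with extended haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlassoc)
```

## The problem

Narcolepsy type 1 (NT1) association studies of the HLA class II region
face a peculiar statistical landscape: almost every case carries the
*DRB5\*01:01:01-DRB1\*15:01:01-DQA1\*01:02:01-DQB1\*06:02:01* haplotype
(the **anchor**), the region is in strong linkage disequilibrium, and
control cohorts are typed without family information, so phase must be
reconstructed before any haplotype can be counted. This package implements
the full chain — allele nomenclature, phase reconstruction, frequency
tables, 2×2 statistics, sequential-elimination analysis of secondary
effects, and carrier-conditional analyses — together with a synthetic
cohort generator that reproduces the statistical structure the chain
assumes, so that every stage can be tested against a known truth.

## Nomenclature

Alleles are WHO-style names `LOCUS*FF:FF[:FF[:FF]]`. Two special forms are
first-class:

* **Null calls.** DRB3, DRB4 and DRB5 are paralogous genes present only on
  some haplotypes; a chromosome carrying none renders as `DRBX*null` and is
  a countable category occupying the single DRB345 slot.
* **Merge groups.** When typing batches differ in resolution, alleles that
  cannot be distinguished across batches are counted as one group
  (`DQA1*03:02//03:03:01`, covering 03:02, 03:02:01 and 03:03:01). Merge
  members match both exactly and as field-prefixes, so one rule covers a
  two-field call from one batch and its three-field refinements from the
  other. Merge application is idempotent, and an allele matching two rules
  is a configuration error.

Formatting a parsed allele reproduces its input; all counting operates on
canonical strings, so category identity is exact.

## Phase reconstruction

**Within families** (`phase_by_descent`): nuclear families are phased by
exhaustive enumeration. Each parent's multi-locus genotype splits into
2^(h−1) distinct haplotype pairs (h heterozygous loci); a child must
receive one intact haplotype from each parent. Recombination within the
DRB345–DQB1 block is disallowed — the block spans well under a centimorgan
and the study design presumes intact transmission. A member is phased when
all transmission-consistent assignments agree (`ambiguity_count = 1`);
symmetric configurations (e.g. both parents carrying the same two
haplotypes) remain unresolved with the admissible count recorded.
Enumeration is exact and cheap because families are nuclear and the block
has at most four loci; we chose exactness over a sampling or EM approach at
this scale.

**Unrelated subjects** (`assemble_by_anchor`): a four-step scheme seeded by
the anchor haplotype and any haplotypes already established by descent:

1. full homozygotes are phased trivially;
2. anchor carriers are phased by subtraction, their remainder haplotypes
   entering the known set;
3. remaining subjects are processed in passes to a fixed point: a genotype
   that decomposes as *known haplotype + remainder* is phased and the
   remainder joins the known set. When several decompositions are
   admissible the one containing the most frequent known haplotype is
   taken (ties by label) and the number of admissible pairs is recorded;
4. when the admissible decompositions disagree **only** in which haplotype
   gets which DRB3/4/5 allele (both candidates match the same allele), the
   frequency preference of step 3 is exactly the published conflict rule —
   assign the matched allele to the more common haplotype — and the
   subject is reported as resolved by that rule.

Subjects with no decomposition stay unresolved: they are excluded from
haplotype-level denominators but keep contributing to allele-level counts,
which is why allele and haplotype tables can have slightly different
denominators. Within-pass processing order is input order; newly
discovered remainders become usable in the next pass, so the result does
not depend on subtle within-pass timing. Allele conservation (hap1 ⊎ hap2
= genotype at every locus) is enforced by construction and re-checked in
the tests.

A design note on ambiguity: for descent phasing, "unresolved" and
"ambiguous" coincide. For anchor assembly we follow the greedy
frequency-preferring rule, so a subject can be assigned a phase *and*
carry `ambiguity_count > 1`; consumers that want only certain phase can
filter on that field.

## Frequency tables and 2×2 statistics

Counting units are explicit: `haplotype_slots` (each subject contributes
two chromosomes; denominator 2N), `carriers` (≥ 1 copy; denominator N),
`subjects` (genotype categories). Categories at ≥ 1% frequency in **any**
group (boundary inclusive) are "common"; the rest are reported separately
as "rare". Every comparison reduces to a 2×2 table of category vs rest:

* odds ratio: cross-product *ad/bc* by default. A conditional
  maximum-likelihood estimator (the hypergeometric MLE reported by
  `fisher.test`) is available via `estimator = "conditional"` because some
  published small-count tables used it; with zero cells the cross-product
  is undefined and reported as missing.
* confidence interval: Woolf's log-scale normal approximation at 95%
  (exact conditional interval under the conditional estimator).
* p-value: Pearson 1-df χ² **without** continuity correction, or the
  two-sided Fisher exact test (probability-mass convention). The default
  selection rule is Fisher when any expected cell is below 5. Reference
  tables we reproduce were evidently inconsistent in this choice — some
  small-cell rows match χ², others Fisher — so the rule is a configuration
  knob and the test actually used is always a column of the output and of
  the run log. Rows whose published p came from the other test reproduce
  to printed precision only under that test.

## RPE: sequential elimination

The relative-predispositional-effects procedure asks what remains after
the dominant effect is removed. Each round tests every remaining category
against the rest; the category with the smallest p-value is the
candidate; it is excluded — its counts removed from both group totals —
when p < α (default 0.05) **and** it has at least `min_case_count = 2`
case copies (categories carried by ≤ 1 case are never considered
significant). Ties on p are broken by the larger |observed − expected|
case count, then label order, making the trace deterministic. The trace
stores every round's complete p-value and test maps, which is exactly the
staggered multi-column p structure of published RPE tables; round 1 equals
the single-shot association by construction.

**Counts mode and the pooled remainder.** Published tables list only the
associated categories plus group totals. `run_from_counts` pools the
unlisted remainder of each block into a background category that restores
the denominators but is *ineligible* for testing or exclusion. This
matters: the pooled remainder of the extended-haplotype block would
otherwise be the round-1 "winner" purely as a pooling artifact (its
deviation aggregates a dozen real categories). Consequently, first-round
p-values in counts mode are exact, while later rounds can differ slightly
from a run on the full (unpublished) category list; with the reference
DRB345 block the full three-round trace happens to reproduce the published
columns to all printed digits.

## Conditional analyses among carriers

Anchor matching is done at a configurable field resolution (default 3,
two-field anchors supported) because the same anchor appears in both
spellings in the literature. Among carriers: the homozygote-vs-heterozygote
2×2, and per second haplotype the carriers-with vs carriers-without table.
The default denominator for second-haplotype percentages is the
heterozygous carriers (each contributes exactly one second haplotype);
because published percentages for these cells are ambiguous about the
denominator, the output reports both the heterozygote and the full-carrier
totals explicitly.

## The synthetic cohort generator

The generator reproduces the structure the analysis assumes, nothing more:

* **Pool.** Sixteen extended haplotypes with fixed frequencies — the LD
  model is simply that only these combinations exist. The anchor is at
  15.3% and three further haplotype frequencies (3.1%, 4.0%, 3.2%) follow
  the reference control cohort; the remaining twelve are the standard
  Northern-European DR-DQ blocks (DR3-DQ2 at 13%, DR1-DQ5 at 11.5%,
  DR11/DR12-DQ7, DR13-DQ6, DR4-DQ8, DR8-DQ4, DR16-DQ5, DR14-DQ5, DR9-DQ9,
  DR10, a DQB1\*03:02 DR4 subtype), chosen once to give realistic allele
  marginals (e.g. DRB4\*01:03:01 near 24%) and to sum to 1 exactly.
* **Population sampling** is Hardy-Weinberg: two independent chromosome
  draws per subject. **Families** draw founder couples the same way and
  transmit one intact haplotype per parent uniformly.
* **Cases** are ascertained by rejection sampling on a multiplicative
  genotype risk (baseline × per-haplotype relative risks, with an optional
  extra factor for designated second haplotypes given one anchor copy).
  With a per-copy anchor relative risk r, case chromosomes are
  independently tilted and the generating haplotype-slot odds ratio is
  exactly r — which is what the end-to-end recovery checks exploit. We
  deliberately model no incidence or vaccination dynamics; FDR are
  unaffected relatives regardless of genotype, matching a comparison-group
  (not screened-negative) design.
* Everything is a pure function of (parameters, seed), and the generating
  phase is retained as ground truth.

What the generator does **not** emulate: genotyping error, missing loci,
population stratification, recombinant haplotypes, rare-allele tails
(every generated allele belongs to one of 16 blocks). Tests passing on
synthetic data therefore validate the machinery — phase logic, counting,
statistics, parameter recovery — not robustness to those real-data
artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 200 subjects for
phase-recovery checks, 40 two-child families for descent checks, and 100
replicates of 1000 cases + 1000 controls for Woolf-CI coverage of a
generating odds ratio of 6 — sizes at which binomial noise is small
relative to the tolerances checked while a full run stays fast on one CPU.
Other conventions: percentages print to 1 decimal, odds ratios to 2,
p-values to 3 significant digits in scientific notation; output rows are
ordered by descending case frequency with label ties broken
lexicographically; all text I/O is UTF-8 with LF newlines; reruns on
identical inputs are byte-identical.

## Known limitations

* Later-round RPE p-values in counts mode depend on the pooled remainder
  (see above); only subject-level mode reproduces full traces exactly.
* The anchor-assembly greedy rule can mis-assign genuinely ambiguous
  genotypes (crossing LD patterns); the `ambiguity_count` field flags
  them, and accuracy degrades gracefully as pool LD weakens (tested).
* Pedigrees must be nuclear (one founder couple, both parents or neither);
  half-specified parentage is rejected rather than guessed.
* No EM-based haplotype-frequency estimation is provided or intended;
  phase comes from pedigrees and anchor assembly only.
* No multiple-testing correction is applied anywhere, by design: p-values
  across HLA categories are strongly dependent, and the RPE structure is
  itself the multiplicity control the analysis relies on.
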