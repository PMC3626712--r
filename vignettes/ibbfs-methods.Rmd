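---
title: "Methods: bound-driven search for SNP-SNP interaction combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bound-driven search for SNP-SNP interaction combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibbfs)
```

## The model

The package operationalizes statistical epistasis as *genotype-combination
enrichment*: a combination fixes one genotype state (coded 1/2/3) at each of
`m` SNPs, a subject matches when it carries every specified state, and the
score of a combination is the raw count difference

$$\mathrm{bound} = \#\{\text{matching controls}\} - \#\{\text{matching cases}\}.$$

Positive maxima mark low-risk patterns, negative maxima high-risk patterns,
and a zero difference is neutral — ranked below any nonzero bound in both
directions, and never reported as a winner. The difference is deliberately
*not* normalized by group size. With unequal groups (the motivating cohort
has 334 controls and 220 cases) the raw statistic is biased toward low-risk
patterns at high background frequencies; we keep the raw form because it is
the statistic the method is defined by, and the odds ratio computed for each
winner provides the size-invariant effect measure.

Genotype codes are opaque states: the package never infers allele identity,
dominance or dosage from them, so any consistent 1/2/3 assignment per SNP
works. The missing code 0 never matches a pattern, but subjects with missing
genotypes stay in the case/control denominators `C` and `N`, which are
constants of the dataset. This fixed-denominator convention is a deliberate
choice (the alternative, per-combination complete-case denominators, changes
the "Other" rows of every report); it keeps all contingency tables
re-summable to `C` and `N`.

## The search

Matching is anti-monotone: extending a combination by one SNP can only shrink
its matched set, and the three children on the added SNP partition the
parent's matched subjects (exactly, when that SNP has no missing data). This
justifies both the empty-node cut-off and expansion by anchored extension.

The search proceeds level-wise:

1. **Base level (order 2) is exhaustive.** All `C(n,2) * 9` two-SNP
   combinations are evaluated. Anchoring the search on a complete two-SNP
   scan is what makes the later greedy levels defensible: every higher-order
   winner must contain some two-SNP sub-pattern, and pairs are cheap.
2. **Feature selection.** Per direction, the top `r = n - m + 1`
   combinations at level `m` survive (the beam narrows as the order grows,
   reflecting that fewer distinct lineages remain informative). The two
   directions run with independent beams: a single signed beam could starve
   whichever direction has the weaker extreme, and the low- and high-risk
   winner lineages are typically disjoint.
3. **Anchored expansion.** Each survivor is extended by every unused SNP
   with each of its three codes, preserving the parent pattern. Children are
   deduplicated (two parents can generate the same child), children matching
   zero cases *and* zero controls are cut off, and children whose absolute
   bound does not exceed the cut-off bound `B = 0` can ride in the beam but
   are never winners. `B` is fixed; no dynamic bound tightening is done —
   observed winners at high orders can have small differences (3–9 subjects
   in the motivating cohort) that tightening with running maxima would have
   pruned.
4. **Ranking.** Within a level, nodes are ordered by direction value
   descending, then by SNP-index tuple, then by genotype-pattern tuple, so
   the output is a pure function of dataset and configuration. Top-`r`
   selection is global per level and direction, not per parent; per-parent
   quotas would re-expand redundant lineages of the same dominant pattern.

`expand_node()` exposes the per-parent expansion with counts restricted to
the parent's matched subjects (the anti-monotone shortcut); internally
`ibbfs_search()` groups candidate children by SNP subset and tallies each
subset once, which is equivalent (tests assert it) and faster in vectorized
R. `nodes_evaluated` counts distinct children whose counts were computed, so
the savings against `es_count(n, m)` are directly reportable.

The exhaustive oracle `exhaustive_best()` guarantees the global per-order
optimum; with the beam rule set to `"inf"` the level-wise search reproduces
the oracle's winners exactly (any nonzero-count combination has a
nonzero-count parent, so pruning never hides a potential winner), which is
the equivalence property the test suite exercises.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_order` | 2 | first, exhaustively scanned order |
| `max_order` | `n` | last order searched |
| `beam_width_rule` | `"paper"` (`r = n-m+1`) | survivors per level and direction; `"inf"` = oracle mode, or any integer/function |
| `cutoff_bound` | 0 | minimum absolute bound for a winner |
| `prune_empty` | `TRUE` | drop zero-match children |
| `top_k` (reports) | 3 | winners printed per level |
| `ci_method` | `"exact"` | conditional exact CI (`fisher.test`); `"woolf"` for the asymptotic closed form |
| `p_method` | `"fisher"` | two-sided Fisher exact; chi-squared with/without Yates as options |
| `zero_correction` | off | Haldane–Anscombe +0.5 on all cells |

The exact conditional CI and Fisher p-value are the defaults because the
2x2 tables of interest are often sparse (high-order winners can match a
handful of subjects); the Woolf interval is undefined at any zero cell and
anti-conservative at small counts. Note the exact CI brackets the
*conditional MLE* odds ratio, which differs slightly from the sample odds
ratio `TP*TN/(FN*FP)` that the package reports as the point estimate.

## Not-estimable propagation and rounding

A zero cell makes the sample odds ratio not estimable; reports print `N.E`
and computation never raises. The convention is asymmetric on purpose:
CC/SN/SP keep whatever values their own denominators allow, but the Average
column, CI and p-value are `N.E` whenever the OR is — an Average computed
while the effect estimate is undefined would suggest a gradable row.
Report rounding is 3 decimal places, half away from zero (`round_half_away`),
not banker's rounding.

## The simulator

`simulate_dataset()` emulates the structure of a small candidate-gene
case-control panel: fixed group sizes (default 220 cases / 334 controls),
seven SNPs drawn i.i.d. per subject from background genotype frequencies
(default Hardy-Weinberg proportions at minor allele frequency 0.3:
0.49/0.42/0.09), optional uniform missingness, and an optional planted
pattern. Planting is one Bernoulli per subject — with probability `p_case`
(`p_control`) the subject's pattern positions are set to the pattern;
otherwise those positions are redrawn from background until at least one
differs. The Bernoulli probabilities are therefore *exact* per-subject match
probabilities, which makes analytic expectations for match counts available
to the tests (`E[matched cases] = C * p_case`, etc.).

What the simulator does **not** model: linkage disequilibrium or haplotype
structure, population stratification, covariates, genotyping error
correlated with phenotype, and quantitative phenotypes. Passing tests
therefore show that the search recovers enrichment planted under
independence; on real data, LD can make several overlapping combinations
near-equivalent, and the deterministic tie-break (not biology) decides their
order.

For the recovery benchmark the planted pattern is the all-heterozygote
pattern `(2,2,2)` on SNPs (2,4,6) with `p_case = 0.25`, `p_control = 0.02`:
under the default background the heterozygote is the most common
non-reference genotype, a realistic configuration for a risk pattern whose
two-SNP sub-patterns remain detectable above the background at level 2 —
the property anchored expansion relies on.

`dataset_from_counts()` is the fixture builder for published contingency
tables whose subject-level data are not deposited: it reconstructs a
synthetic cohort with exactly the printed matched counts (non-matching
subjects differ from the pattern at its first SNP via a cyclic code shift, a
deterministic minimal perturbation; remaining SNPs take a filler code). Such
a cohort reproduces every statistic that depends only on the matched counts
— which is exactly the set of quantities the package verifies against the
published tables.

## Problem sizes in the test suite

The suite checks oracle equivalence on twenty 200-subject, 6-SNP cohorts
across all orders and both directions, planted-pattern recovery on one
hundred 554-subject, 7-SNP replicates, and the partition/anti-monotonicity
invariants on over a thousand randomized instances; the whole suite runs in
well under a minute on one core. These sizes give the properties thousands
of distinct assertions while staying in the regime (n <= 7) where the
exhaustive oracle is cheap; the search itself handles larger panels, but
oracle-checked testing beyond n ~ 10 buys little additional evidence at
rapidly growing cost.

## Known limitations

* The raw count difference is group-size biased; compare directions only
  through the per-winner odds ratios.
* With the default narrowing beam the search is heuristic above the base
  level: soundness (never beating the oracle) is guaranteed, completeness is
  not — a high-order optimum whose every two-SNP sub-pattern is weak can be
  missed. The `"inf"` beam restores completeness at exhaustive cost.
* P-values are not corrected for the multiplicity of the combination scan;
  they grade single tables, not the search.
* The exact CI method of legacy web calculators varies; printed intervals
  from older analyses may differ in the far decimal places from
  `fisher.test`'s conditional interval.
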