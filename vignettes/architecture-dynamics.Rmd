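---
title: "Lineage-based dynamics of protein domain architecture content"
author: "archevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-based dynamics of protein domain architecture content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archevo)
```

## The model

A protein's *domain architecture* is the ordered N-to-C arrangement of its
Pfam domains, written as a maximal run-length encoding: a protein with three
consecutive LysM motifs followed by a protein kinase domain is
`"LysM(3) PKinase(1)"`. The encoding is over *consecutive* identical
domains, so an interleaved arrangement `A B A` remains three runs — the
string preserves the linear domain order, which is what distinguishes
architectures from mere domain content. The *genomic dosage* of an
architecture is the number of proteins in one genome bearing it; the
central data object of the package, `ArchitectureContent`, is the
architecture-by-species dosage matrix (a `SummarizedExperiment` with one
`"dosage"` assay and per-species proteome totals in `colData`).

Architectures are built from PfamScan-style per-domain hit tables. Hits are
retained at a per-domain E-value cutoff of 1e-2 (the threshold used for the
original 14-genome scan this package is organized around), and overlapping
hits within one protein are resolved by keeping the hit with the smallest
E-value (ties: smaller start, then lexicographic domain name). The overlap
rule is this package's own addition — it guarantees deterministic,
non-overlapping input to the string builder without reproducing Pfam's
clan-competition logic. Domain identity uses the family *name*, as in
printed architecture strings; accessions travel as metadata only.

## Lineages, patterns and the prevalence filter

Species are grouped by a `LineageScheme` into ordered lineages with
per-lineage majority thresholds. The default scheme holds the 14 green
plant genomes: five algae (majority 3 of 5), the two early-diverging land
plants moss and spikemoss (2 of 2), three monocots (2 of 3) and four
dicots (3 of 4). An architecture's *pattern* is the subset of lineages in
which it is majority-present, written as concatenated labels (`"BCD"` =
land plants, `"CD"` = angiosperms, `"ABCD"` = universal); 15 non-empty
patterns exist over four lineages.

Classification proceeds in the order: species-specific architectures
(positive dosage in exactly one species) are split out first; the
remaining shared architectures pass the *prevalence filter*. Under the
default strict rule an architecture is prevalent only if the majority
threshold is met in **every** lineage where it occurs at all, so an
architecture carried by ten species across three lineages but by a single
outlier dicot is removed entirely rather than re-patterned. This mirrors
the published analysis, which removes such less-commonly-represented
architectures instead of reassigning them; the alternative
(`prevalence = "majority"`, re-pattern on majority lineages only) is kept
as an option.

```{r patterns}
sim <- simulateContent(simulationConfig(
    patternMix = c(ABCD = 30L, BCD = 10L, CD = 5L, A = 4L),
    speciesSpecificRate = 2L, seed = 7L))
summarizePatterns(assignPatterns(sim$content, defaultLineageScheme()))
```

## Genome profiles and the normality assessment

Per-genome profiles report the fraction of the proteome with a predicted
architecture, the fraction of species-unique architectures, and the
proteome fractions in the single- / double- / triple- / >=4-domain
categories. Two denominator conventions matter and are fixed deliberately:
category fractions divide by the proteome total (so they sum exactly to
the predicted fraction), while the unique fraction divides by the species'
distinct-architecture count — the only pairing that makes the published
per-genome profile table internally consistent. The domain-count category
is by total domain *instances* (`"LysM(3) PKinase(1)"` counts as four),
not by number of runs.

Cross-genome homogeneity is assessed with the Anderson-Darling composite
normality test: values are standardized by their own mean and standard
deviation, the statistic is adjusted for small samples as
$A^{2*} = A^2(1 + 0.75/n + 2.25/n^2)$, and the p-value uses the
D'Agostino–Stephens piecewise exponential approximation for the
estimated-parameters case. The test is affine invariant, so proportions
and percentages give identical p-values. On the bundled reference profiles
of the 14 genomes:

```{r ad}
andersonDarling(referenceProfiles()$frac_predicted)
```

The published summary figures quoted alongside such profiles as
"mean ± SE" numerically match the sample standard deviation; the package
reports `mean`, `sd` and `se` separately and labels them correctly.

## Expansion testing and the bootstrap adjustment

Lineage-wise expansion of an architecture is tested on the natural-log
genomic dosages with a Welch (unequal-variance) two-sample t-test for each
of the six ordered lineage pairs, treating species within a lineage as
exchangeable replicates. The Welch flavor is a deliberate choice for tiny,
unbalanced lineage samples (2-5 species). Species with zero dosage are
excluded from their lineage's sample rather than patched with a
pseudo-count, because prevalent architectures are present in lineage
majorities and `log(x + 1)` distorts fold-changes at dosages of 1-2; a
`pseudoCount` option provides the alternative. Architectures with fewer
than two carriers in either lineage are flagged untestable, never silently
dropped. Before any test, per-species divisors correct known biases
(canonically maize / 3 for its unmasked annotation, soybean / 2 for its
recent duplication), and an optional whole-genome-duplication divisor
(8 or 16) re-normalizes angiosperm dosages to a presumed pre-WGD ancestral
genome — in the noiseless limit of exact 8-fold duplication this
normalization cancels every expansion signal exactly (t = 0), which is
verified as an invariant test.

Multiplicity over architectures is handled per lineage pair with a
Westfall–Young free step-down max-|t| bootstrap (the original analysis
names only a bootstrap adjustment; the exact procedure is unrecoverable,
so the package fixes a standard, seeded one with B = 1000 by default). Two
numerical safeguards are required at these sample sizes and are part of
the method's definition here:

* **Null enforcement by centering.** Each architecture's log dosages are
  centered by their own lineage mean before species labels are resampled.
  Without this, genuinely expanded architectures contaminate the pooled
  "null" with bimodal values and the resampled maximum swamps every real
  signal.
* **Variance-stabilized statistic.** Both the observed and resampled
  statistics inside the adjustment use a moderated denominator
  $\sqrt{s_1^2/n_1 + s_2^2/n_2 + s_0^2}$ with $s_0$ the family median
  standard error. With 2-4 draws per resampled group, the unmoderated
  t statistic has a heavy tail (near-constant groups produce arbitrarily
  large values) that otherwise dominates the maximum. Raw p-values remain
  pure Welch; `p_adj >= p_raw` is enforced, as is monotonicity over the
  observed ordering.

An architecture with at least one significant expanding pair (adjusted
p at or below the chosen level, later mean above earlier) counts as
showing a trend of expansion; `classifyExpansion()` reduces the six pair
flags to a named class such as "expanded from algal into all land
lineages". One granularity limit is worth knowing: for the
five-versus-two algal/early-diverging pair, redrawing the extreme split
has probability about $(2/7)^2 (5/7)^5 \approx 0.015$, so adjusted
p-values for that pair cannot fall below roughly 0.015 and per-pair
detection at the 1% level is structurally impossible there regardless of
effect size. Detection claims therefore rest on the monocot and dicot
pairs, whose larger samples push the floor well below 1%.

## Domain novelty

Architectures confined to the angiosperm-side patterns (`CD`, `C`, `D`)
are decomposed into constituent domains, and a domain is *newly emerged*
iff it occurs in no architecture whose raw occurrence (any species,
prevalence not required) includes the algal or early-diverging lineages.
Novelty is thus defined purely by architecture-content absence — no
sequence homology search backs it, by design. Contingencies split the
scope's architectures into single-domain versus multi-domain (same
instance-count rule as profiling) and tally distinct domains by novelty;
Pearson chi-square goodness-of-fit tests with no continuity correction
compare the newly-emerged/pre-existing split against 50:50 expected
proportions. The 50:50 default is reverse-engineered: it reproduces the
published statistics 16.49, 5.4, 0.015, 26.16 and 70.74 exactly from the
printed counts. One published dicot multi-domain value (10.91) does not
match the formula (which gives 10.31); the package implements the
formula, not the misprint. A third published row of test statistics could
not be reverse-engineered from any printed counts; `gofTest()` accepts
arbitrary expected proportions so the hypothesis space can be explored,
but no default reproduces it and it is asserted nowhere.

```{r gof}
gofTest(c(11, 40))
```

## The simulator: what it emulates and what it does not

`simulateContent()` generates dosage matrices with known ground truth:
architectures planted per pattern (every member species present before
dropout), per-cell copy numbers from a configurable dosage model,
expansion rules that multiply target-lineage dosages by a fold-change, WGD
inflation modeled per retained copy as `Binomial(2^rounds - 1, retention)
+ 1` (so incomplete retention of duplicated copies is a single
parameter), per-cell dropout that manufactures less-commonly-represented
architectures, and per-species unique architectures. Domains of
late-confined architectures can come from a reserved namespace, making
novelty ground truth unambiguous. The default dosage model is geometric
with mean 3 truncated at one copy — a loose match to the observation that
copy numbers of individual architectures range from one to several
hundred, with the heavy tail available through the negative-binomial
option.

`paperScalePreset()` freezes the study-scale conditions: the published
per-pattern counts (1944 universal down to single-count patterns, with
the one unprinted cell set to 21 by subtraction from the 3046 prevalent
total), zero dropout, and 390 species-specific architectures per species.
On this preset the pattern summary reproduces the published arithmetic —
3046 prevalent, 347 lineage-specific, a 63.8% universal share — exactly
and deterministically.

The generator exists to test the pipeline's statistics, not to model
plant genome evolution: it simulates no sequences, no evolutionary rates,
no phylogenetic correlation between lineages, and no genuine gain/loss
process (patterns are planted, not evolved). Passing tests therefore
demonstrate that the statistical machinery recovers planted structure
under the stated noise — not that real genomes satisfy the machinery's
assumptions.

## Numerical choices and problem sizes

Tie-breaks and degenerate cases are fixed as follows: overlapping hits
resolve by (E-value, start, name); equal lineage samples give t = 0 and
p = 1; separated constant samples give infinite t and p = 0; a zero
standard error in the Anderson-Darling input or fewer than five values is
an error; chi-square tests require positive expected proportions; the
bootstrap requires B >= 100 and a fixed seed. Pattern labels always
concatenate in scheme order regardless of input order, and the scheme
requires single-character lineage labels so patterns stay unambiguous.

The test suite exercises the full stack at the sizes a laptop handles in
minutes: pattern-law checks on 1000 random 14-species fixtures,
chi-square oracle equivalence on all count pairs summing to at most 200,
a full emit/parse round trip at study scale (about 8500 architectures,
roughly 10^5 synthesized proteins) and planted-expansion recovery over
200 seeded replicates at B = 1000 with lineage sizes (5, 2, 3, 4), where
detection of an 8-fold planted expansion exceeds 95% at the 1% level and
the family-wise error under the global null stays at or below 5%.

## Known limitations

* The prevalence rule, denominators and 50:50 expectations are fixed to
  reproduce one published analysis; other corpora may need the provided
  alternatives (`prevalence = "majority"`, custom `gofTest()`
  proportions, `pseudoCount`).
* Species within a lineage are treated as exchangeable replicates; no
  phylogenetic comparative correction is applied or planned.
* Novelty calls are architecture-content calls, not homology calls: a
  domain present in early lineages but annotated only in late genomes
  will be miscalled newly emerged.
* The bootstrap adjustment is a reconstruction of an underdocumented
  procedure; at significance boundaries its counts will differ from the
  originally published expanded/unchanged split, which also depended on
  the real 14-genome data.
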