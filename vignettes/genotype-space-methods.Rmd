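---
title: "How genospace measures the organization of enzyme functions in sequence space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How genospace measures the organization of enzyme functions in sequence space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(genospace)
library(dplyr)
```

## The question and the quantities

Protein sequence (genotype) space is the set of all amino-acid
sequences of a given length, with distance `d` measured as the percent
of differing positions.  Sequences that keep the same structure form
far-reaching networks in that space, and a long-standing question is
how *functions* — here enzyme activities, labelled by 4-level EC
numbers — are laid out over those networks.  genospace implements
three families of statistics over annotated, aligned protein sequence
sets:

1. **Structural promiscuity** `R_F`.  For a function `F`, let `f(i)`
   be the fraction of `F`'s sequences folding into structure `i` (a
   CATH-style homologous superfamily label).  With `H` the Shannon
   entropy (natural log) of the nonzero `f(i)` and `N` the total
   number of structures in the dataset,
   `R_F = H / ln N` lies in `[0, 1]`: 0 when one structure carries
   the function, 1 when every structure carries it equally.
   **Functional versatility** `V_S` is the mirror image (functions per
   structure, normalized by `ln M` with `M` the total number of
   functions).  Normalizing by the dataset-wide totals — rather than
   the per-function structure count — is deliberate: it makes values
   comparable across functions and matches the definition of maximal
   entropy as a uniform spread over *every* structure.

2. **Neighborhood diversity** `F_u`.  A neighborhood `N_G(r)` is the
   ball of all sequences within distance `r` of `G` (inclusive, so `G`
   is always a member).  For two balls with function sets `S1`, `S2`,
   `F_u = (|S1| + |S2| - 2|S1 ∩ S2|) / |S1 ∪ S2|` is the fraction of
   functions unique to one of them — algebraically the Jaccard
   distance of the two sets.  `F_u` is aggregated over sequence pairs
   into a (distance bin × radius) grid: bins of width 5 over
   `[0, 100]` (20 bins, half-open except the last), per-cell mean,
   pair count and standard error (sample sd / √n, missing for a single
   pair).  Empty cells are reported as empty, never as zero.

3. **Protein families.**  A family is a single-linkage connected
   component of one structure's sequences with edges at `d < 70`
   (strict, matching the usual limit of recognisable common ancestry).
   Single linkage is the weakest relation consistent with
   "co-membership below the threshold" and is order-free and
   deterministic.  The monofunctional-family subset is the control
   that collapses neighborhood diversity below the family divergence
   scale.

## Distance and filtering conventions

Pairwise distance is the percent of mismatching columns after
*pairwise deletion*: columns where either sequence is gapped are
excluded, so `d = 100 · mismatches / n_compared`.  Pairs with no
comparable column have undefined distance and are dropped (and
counted).  The unknown residue `X` is legal input but counts as a
mismatch against everything, including another `X` — a conservative
choice for a character that asserts ignorance.  Distances are in
percent everywhere.

The filter funnel mirrors standard practice for curated enzyme sets,
in this order: (1) drop sequences with 50 or fewer ungapped residues
(single-domain floor; the threshold is exclusive, "longer than 50");
(2) drop sequences with more than 10% gaps, then whole alignments in
which more than 10% of the remaining columns contain any gap; (3) a
greedy pass that keeps a sequence only if its identity to every
already-kept sequence is at most 99%.  Gap filters run before the
identity cap so identity is computed on cleaned alignments; the greedy
pass uses input order as priority, making it deterministic.  Every
stage reports its drop count, and the funnel conserves sequences
exactly (input = output + drops), which the tests assert.

Cross-structure comparisons require sequences of one length.
`resample_sections()` therefore cuts, per resample, one uniformly
random contiguous window of 100 columns (default) from every alignment
at least that wide, re-applies the gap filters to the windows, and
repeats this 10 times (default).  Each (structure, resample) pair
draws from its own deterministic RNG substream, so adding or removing
one alignment never changes the windows cut from the others, and a
fixed seed reproduces the windows bit for bit.  Downstream, grids from
the resamples are combined cell-wise (mean and sd across non-empty
samples).

## The synthetic generator and what it emulates

No curated assembly of sequences with joint structure and function
annotation is bundled, so validation rests on `generate()` with
planted ground truth.  The generative model:

* Each structure hosts several **families**, each descending from an
  independent ancestor drawn uniformly over the 20 amino acids.
  Families are stars of **subfamilies**: a subfamily ancestor is a
  per-site mutant of the family ancestor (site probability `p1`), and
  each member a per-site mutant of its subfamily ancestor (`p2`).
* Mutation resamples a site to a uniform amino acid (possibly the
  same).  A site then differs between two sequences exactly when at
  least one lineage resampled it and the final draws disagree, so the
  expected divergence is `95 · (1 − (1 − c1)(1 − c2))` percent for
  chain resampling probabilities `c1`, `c2`
  (`expected_pairwise_divergence()`).  `p1` and `p2` are solved from
  this closed form so that within-subfamily and within-family
  divergences hit their targets (defaults 15 and 55 percent — the
  scale of typical same-structure-and-function divergence), and
  independent ancestors give 95 percent between families.  The tests
  verify the closed form against brute-force simulation.
* A family is **multifunctional** (probability `p_multifunctional`)
  when its subfamilies carry *distinct* functions; a monofunctional
  family's subfamilies share one.  Tying function turnover to
  subfamily boundaries is the one place the generator imposes
  biological realism the statistics depend on: if functions were
  assigned to members independently of their position in sequence
  space, two sequences a handful of substitutions apart would
  routinely differ in function, and small-radius neighborhoods would
  look maximally diverse at all distances — the opposite of what real
  enzyme families do.
* **Promiscuity** arises two ways: spontaneously (a new family reuses
  a function from another structure with probability `p_promiscuous`)
  and by design (`plant_promiscuous_k` places one designated function
  into exactly one family in each of `k` structures, giving a known
  target `R_F ≈ ln k / ln N` for balanced counts).
* **Gaps** are confined to a small set of per-structure hotspot
  columns (default 5% of columns; per-site gap probability 0.3 within
  them).  Real alignments concentrate gaps in indel-prone loops; had
  gaps been i.i.d. over all columns, essentially every column of a
  large alignment would contain one and the column-gap filter would
  discard the whole alignment.

Three presets document the study conditions used in tests:
`tiny` (≤ 12 sequences, for exhaustive brute-force comparison),
`tim_like` (one structure, 16 families of mixed functionality — the
testbed for neighborhood-diversity patterns and the monofunctional
control), and `multi_structure` (6 structures, ≈ 1,000 sequences, a
function planted across 4 structures — the testbed for promiscuity and
family recovery).  These sizes keep the full validation suite at
around a minute on one CPU while leaving hundreds to thousands of
pairs per occupied distance bin.

What passing these tests shows — and does not.  The generator shares
with real data the features the statistics are sensitive to: skewed
per-family counts, family/subfamily distance structure, mono- and
multifunctional families, reused functions across structures, gapped
columns.  It does not model substitution-matrix effects, indel
evolution, phylogenetic tree shape within subfamilies, or database
bias; agreement on synthetic data therefore validates the machinery,
not any empirical claim about real enzymes.

```{r patterns, fig.width = 6, fig.height = 3.5}
cfg <- emulate_paper_shape("tim_like", seed = 5)
g <- generate(cfg)
d <- all_pairwise_distances(g$dataset)
rec <- fu_for_pairs("all", d, g$dataset, radii = c(5, 10))
plot_fu_curves(aggregate_grid(rec))
```

The curve reproduces the qualitative pattern the statistics were built
to expose: neighborhoods of nearby sequences share almost all their
functions, diversity rises with the distance between neighborhood
centers, and beyond the family divergence scale virtually all
functions are unique to one neighborhood.  Restricting to
monofunctional families (`monofunctional_subset()`) collapses the
curve to zero below that scale.

## Numerical and design choices

* Natural logarithms throughout the entropies; `R_F`/`V_S`
  normalization needs at least two structures/functions, otherwise the
  computation aborts rather than divide by `ln 1`.
* Ball membership is inclusive (`d ≤ r`), and a ball always contains
  its own center, so a center's own function is always in its set.
* Pairs whose two balls both carry no annotated function have
  undefined `F_u` (0/0); such records are skipped and counted, never
  imputed.
* `top_promiscuous()` breaks ties by structure count, then label, so
  rankings are reproducible.
* Family edges use strict `d < threshold`; a pair at exactly the
  threshold is not joined.
* The EC level is a parameter everywhere (level 1 analyses run from
  the same code as level 4); labels must carry numeric descriptors at
  all four levels, and annotation rows that do not are dropped with a
  count.
* Undefined distances (no shared ungapped column) drop the pair, with
  a counter, at every stage that meets them.
* `sample_pairs()` draws unordered pairs uniformly without replacement
  within one draw by sampling linear indices of the upper triangle;
  repeated draws (e.g. per resample) are independent.
* Heatmap cells with `r < d/2` (balls that cannot overlap) are flagged
  in the grid output, not treated specially in any statistic.

## Limitations

Real-data headline numbers (the share of monostructural functions,
maximal `R_F`, family-pair sharing rates) depend on a specific curated
assembly of sequence, structure and function annotation that is not
redistributable here; the package computes all of these quantities but
ships no claim about their empirical values.  Entropy estimates are
plug-in estimates without small-sample bias correction, which is
visible for functions with few sequences; the sequence-count control
(`mean_structure_frequency_per_function()`) and the subsampling options
exist precisely because of that.
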