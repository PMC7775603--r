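---
title: "Methods: distance-based phylogenetics from syntactic parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based phylogenetics from syntactic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmphylo)
```

## The data model

A parameter matrix records, for each language and each binary syntactic
parameter, one of four states. `+` is the non-default value, set by the
learner only when positive evidence (a licensing construction) is present in
the input; `-` is the default, the state a grammar keeps absent such
evidence. `0` marks a *null* state: the parameter is rendered irrelevant or
fully predictable by the states of other parameters, and so carries no
independent information. `?` marks a value that was simply not observed.
`pcmphylo` treats `0` and `?` identically in every comparison (both
excluded) but tracks them separately in summaries, because they have
different epistemic status: a null is a *consequence* of the grammar, an
unknown is a gap in the data.

The implicational structure matters quantitatively. In the reference
Eurasian dataset of 69 languages by 94 nominal parameters, about 45% of all
cells are null, and an average pair of languages is comparable on only ~39
parameters (range 14–66). Any analysis of such data must therefore restrict
every pairwise comparison to the positions valued in both languages, rather
than imputing or discarding whole characters. Where explicit dependency
conditions are available, `validate_dependencies()` checks that the nulls
are exactly the cells whose condition fails; the package treats the matrix's
nulls as authoritative when no conditions are supplied, since the full
implication formulas live in the parameter system's defining literature
rather than in any single dataset. Conditions are conjunctions of
(parameter, required state) terms; this covers the simulator's output and
the common single-controller case, and keeps validation semantics
unambiguous.

## Distances

With joint counts N++, N+-, N-+, N-- over the mutually valued positions,
the two metrics are

- Jaccard: (N+- + N-+) / (N+- + N-+ + N++),
- normalized Hamming: (N+- + N-+) / (N++ + N+- + N-+ + N--).

The Jaccard form embodies the asymmetry of the state semantics: two
languages sharing a default `-` share an *absence*, which is weak evidence
of common history, so `-/-` identities are dropped from the denominator. It
follows algebraically that Jaccard ≥ Hamming for every pair, with equality
exactly when the pair has no `-/-` matches (or no differences at all); the
test suite asserts this as a property.

A pair whose Jaccard denominator is zero has an *undefined* distance. This
cannot happen in the reference dataset (its minimum Jaccard support is 12,
for Korean–Japanese), but sparse or simulated matrices can produce it, so
`pcm_dist()` offers two policies: `error` (default; names the pair) and
`flag` (records `NA` for tools that tolerate missing distances). Distances
are kept at full floating precision internally; file outputs round to 3
decimals, matching conventional reporting precision.

## Trees

`upgma()` is written in the package rather than delegated, because two
conventions must be pinned down: (i) cluster-to-cluster distances are
size-weighted means of the original pairwise distances (true average
linkage), and (ii) when several pairs tie for the minimum, the pair whose
sorted pair of smallest member labels is lexicographically smallest merges
first. The tie-break makes output deterministic across platforms and input
orders, which matters for reproducible bootstrap counts. The result is a
rooted ultrametric `phylo` (all root-to-tip paths equal; merge height d/2).
Tests verify exact agreement with a brute-force average-linkage oracle on
random small matrices and exact recovery (Robinson–Foulds 0, matching node
heights) of random ultrametric trees from their path metrics —
`hclust(method = "average")` and `phangorn` serve as independent
cross-checks, never as the implementation.

Bootstrap support resamples the parameter *columns* with replacement (the
standard character bootstrap), recomputes distances and the UPGMA tree per
replicate, and reports for each clade of the original topology the
percentage of retained replicates containing it. Replicates with any
undefined pair are discarded and counted. Support is reported on the
original topology by default because that is the tree the analysis
interprets; a majority-rule consensus mode (`consensus = TRUE`) is available.
The replicate count and resampling variant used for any published figure of
this kind are typically under-documented, so bootstrap values are treated as
descriptive, not as quantities to reproduce.

Gold-Standard scoring is deliberately strict: a group counts as recovered
only when some node's descendant tip set equals the group exactly — no
partial credit — because the downstream claim ("the tree captures the
established families") is about exact clades. The packaged table carries the
24 published groups; the controversial Altaic grouping is excludable by
argument, giving the 23-group denominator used for headline figures.

## Ordination and heatmap

`pcoa()` double-centers the squared distances (-1/2 J D² J) and
eigendecomposes. Jaccard matrices are generally non-Euclidean, so negative
eigenvalues occur; they are reported but excluded from variance fractions
(fraction = eigenvalue / sum of positive eigenvalues). This is the
convention under which published variance-explained figures for such data
are stated; the alternative (absolute-value weighting) would shrink every
fraction and is not used. Axis signs are arbitrary, as in any
eigendecomposition.

The heatmap product is a plot-ready table, not an image: the matrix is
reordered by the UPGMA leaf order (subtrees rotated so the
lexicographically smallest label leads, making the order deterministic and
permutation-invariant), then each cell is binned relative to the median
off-diagonal distance — cells at or below the median form the "cool" half,
cells above the "warm" half, each half cut into equal-width shade bins. Ties
at the median are assigned to the cool side, i.e. the cool interval is
closed at the median; constant halves collapse to a single bin.

## Tree-likeness

For each 4-subset of taxa the three pairing sums m1 ≥ m2 ≥ m3 of the six
pairwise distances are formed. On an additive (tree-realizable) metric the
two largest sums are equal (the four-point condition), so

- delta = (m1 - m2) / (m1 - m3) measures conflict in [0, 1], with the
  degenerate all-equal case scored 0 by convention;
- the Q-residual is (m1 - m2)² computed on distances pre-scaled so the mean
  off-diagonal distance is 1, making it scale-invariant.

Per-taxon scores are arithmetic means over the C(n-1, 3) quartets containing
the taxon, accumulated in a streaming pass over `combn(n, 4)` (no quartet
list is materialized; the 69-taxon case enumerates ~8.6e5 quartets in a few
seconds). Published Q-residual values for comparable analyses were computed
from a NeighborNet split network rather than directly from the distance
matrix, and the normalization conventions of that route are not fully
documented; the distance-based quartet form implemented here is therefore
cross-checked against its own definition and against additivity (zero on
tree metrics), but numeric agreement with network-derived Q-residuals is
not claimed. Delta-scores do not suffer this ambiguity.

## The simulator

The generative model used to validate the pipeline:

1. **Tree**: a Yule (pure-birth) process run to the requested number of
   tips, sampled one waiting time after the last split, and clock-rescaled
   to unit root-to-tip depth. All rates below are per unit of that depth.
2. **Characters**: each parameter evolves independently along branches as a
   two-state CTMC simulated exactly by exponential waiting times ("-" to
   "+" at the gain rate, "+" to "-" at the loss rate), which supports a
   complete event log with branch timestamps.
3. **Implicational nulls**: a configurable fraction of parameters receive a
   single-controller condition requiring `+` on an earlier-indexed
   parameter, mimicking the head-of-implication-chain structure of real
   parameter systems. The condition is evaluated at every node: unmet means
   the state is `0`; a parameter becoming newly defined initializes to the
   default `-`. Nulls therefore cascade down dependency chains, as they do
   in real matrices.
4. **Borrowing**: after evolution, configured donor–recipient leaf pairs
   copy a uniform sample of the donor's defined parameters, and the
   recipient's dependent parameters are re-evaluated so every null stays
   certified by its condition (the test suite checks this invariant with
   `validate_dependencies()`).

Defaults were calibrated once against the reference dataset's marginal
statistics — null share ~45%, "+" share among valued cells ~39%, median and
maximum Jaccard distance ~0.43/0.86 — giving gain 0.18, loss 0.27
(asymmetric, stationary "+" frequency 0.4: grammaticalized features are
gained more readily than dropped), a root carrying `+` on 40% of its
defined parameters (a realistic ancestral grammar rather than an all-default
one), and a 55% dependency fraction. What the simulator does **not**
emulate: the real parameters' non-uniform rates of change (micro-parameters
discriminating dialects evolve faster than macro-parameters), the actual
94-parameter implication formulas (conditions are sampled, single-ancestor,
`+`-requiring), areal pressure beyond pairwise leaf-level borrowing, and any
family-correlated sampling of taxa. Consequently, passing recovery tests
shows the pipeline is correct and consistent under the assumed model — it
does not show that real syntactic data are this well-behaved, nor the
converse.

## Numerical and design choices

- Merge heights, branch lengths and distances are computed in double
  precision; Newick serialization keeps 15 significant digits, so
  round-trips are stable to 1e-9.
- UPGMA tie-breaks and heatmap leaf-order rotations are lexicographic:
  determinism is preferred over any data-driven ordering heuristic.
- PCoA eigenvalues within 1e-9 (relative) of zero are treated as zero.
- Undefined distances are values (`NA`), not exceptions, except where a
  stage cannot proceed (UPGMA, PCoA, quartets), where they abort naming the
  pair.
- All randomness (bootstrap, simulation, recovery experiments) flows from a
  single integer seed per call; replicate r of a recovery experiment uses
  seed + r - 1, keeping runs reproducible and replicates independent.
- Reported summary conventions: mean/median "+" counts and overlaps are
  rounded to integers, distances and scores to 3 decimals, percentages to
  integers.
- Problem sizes in the test suite were chosen to keep the whole run light:
  oracle comparisons use 4–7 taxa where exhaustive enumeration is exact,
  stationarity uses 1e4 leaf draws, and the consistency sweep uses 50
  replicates per characters-count at 20 taxa. These sizes give the
  assertions comfortable statistical margins while completing in well under
  a minute.

## Known limitations

- Dependency conditions are conjunctions; disjunctive conditions in a real
  parameter system would need encoding as separate parameters or an
  extension of the validator.
- `0` and `?` are merged on NEXUS export (both become the missing symbol),
  so the export–reimport round trip loses the null/unknown distinction, by
  construction.
- Whether published cross-family "average distance" figures pool all pairs
  or only cross-family pairs is ambiguous in prose; `cross_group_mean()`
  computes the cross-pair mean, the reading consistent with the quoted
  values, and the pooled alternative is one `mean()` away from the distance
  matrix.
- Bootstrap support values and Bayesian posterior topologies are outside
  the package's reproduction scope: the former because the published
  procedure's details are unavailable, the latter because character-based
  Bayesian inference is delegated to external tools via `write_nexus()`.
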