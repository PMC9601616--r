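---
title: "Methods: multilocus barcode evaluation with barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus barcode evaluation with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A DNA barcode is useful for a group of organisms when sequence distances
within species are systematically smaller than distances between species
(the "barcoding gap"), and when conspecific individuals cluster together
on a phylogenetic tree. `barcodegap` quantifies both properties for any
set of pre-aligned nuclear markers — singly and in every combination — and
reports a per-marker-set *species discrimination rate*. The package was
built with fungal multilocus barcoding in mind (markers such as ITS,
*EF1-α*, *RPB1*, *RPB2*, where taxonomically difficult genera like true
morels mix highly variable and nearly invariant loci), but nothing in the
machinery is taxon-specific.

## Distances

Two pairwise distances are implemented, both under **pairwise deletion**:
any site where either sequence carries a gap (`-`), `N`, or an IUPAC
ambiguity code is excluded for that pair only. This mirrors the default of
the common alignment GUIs, keeps per-pair information maximal, and makes
the number of comparable sites an explicit, reported quantity
(`comparable` matrix of `distance_matrix()`).

* **p-distance**: mismatches over comparable sites — the uncorrected
  proportion.
* **K2P (Kimura 2-parameter)**: with $P$ and $Q$ the transition
  (A↔G, C↔T) and transversion proportions,
  $$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$
  The correction is undefined when $1-2P-Q \le 0$ or $1-2Q \le 0$
  (substitution saturation). The package **errors by default**, naming the
  offending pair; an explicit `saturation = "cap"` mode substitutes a
  ceiling `d_max` (default 5 substitutions/site) for exploratory sweeps.
  We chose erroring as the default because a saturated barcode pair
  usually indicates misalignment or a marker unsuited to the group, and
  silently capped distances would distort the gap statistics.

Since the correction is convex, $d_{K2P} \ge p$ always, with equality only
at $p = 0$; this is asserted numerically in the test suite.

## The two discrimination criteria

**PWG-distance (barcoding-gap) criterion.** A species is successfully
identified when its *minimum interspecific* distance is strictly larger
than its *maximum intraspecific* distance. Ties fail. Both sides are
evaluated under one user-chosen model (default K2P) for internal
consistency; a `pwg_mixed` flag reproduces the mixed reading found in
parts of the barcoding literature (intra side under p-distance, inter side
under K2P). We did not add any pooled-overlap veto on top of the
per-species inequality: "no obvious overlap" has no agreed quantitative
form, and the strict inequality is itself the operational criterion.

**NJ-tree criterion.** A neighbor-joining tree is built from the distance
matrix; nonparametric bootstrap (column resampling, default 1000
replicates) attaches support percentages to its internal edges; a species
succeeds when its individuals are monophyletic — on an unrooted tree, some
edge's bipartition equals exactly that species' tips — with support
strictly above the threshold (default 50%). Monophyletic species whose
subtending edge carries no support annotation (supports not computed) fall
back to topology alone, with a warning.

**Singletons.** Species sampled once have no intraspecific pairs and are
trivially monophyletic. By default they count as successes (with their
maximum intraspecific distance taken as 0, so a positive minimum
interspecific distance suffices), because published denominators typically
track the full species count; `singleton_policy = "exclude"` drops them
from both numerator and denominator. The reported `n_species` always
states the denominator actually used.

**The rate.** `rate_pct = 100 · n_success / n_species`, rounded half-up
to two decimals (`round_half_up()`, not banker's rounding). The same
half-up rule produces the variability percentages
(`pct_snp = 100 · SNPs / length`,
`pct_variable = 100 · (SNPs + indels) / length`).

## Site classification

A column containing any gap is an **indel site**. A column where at least
two distinct unambiguous nucleotides occur is a **SNP site**; ambiguity
codes and `N` never create polymorphism. A gap column whose gap-free rows
are still polymorphic counts in *both* tallies by default
(`count_gap_snps = TRUE`), because the variable-site percentage is defined
additively as (SNP sites + indel sites) / length; the
`count_gap_snps = FALSE` toggle gives indel classification strict
precedence for comparison with tools that count each column once.

## Neighbor joining, exactly specified

The agglomeration joins the pair minimising
$Q_{ij} = (N-2)\,d_{ij} - r_i - r_j$; ties are broken deterministically by
the first (row, column) pair in the current matrix ordering. Negative
branch lengths are clamped to zero with the deficit moved to the sister
edge, preserving the path length through the new node. NJ is consistent on
additive matrices — the test suite checks exact topology recovery and
path-length reproduction to 1e-9 on random additive matrices, and
cross-checks topologies against an independent NJ implementation on noisy
matrices.

Bootstrap supports are mapped onto the reference tree built from the full
alignment (not onto a consensus). Replicate $r$'s column resample depends
only on (seed, $r$, attempt), so runs are bit-reproducible and
embarrassingly restartable; a replicate whose resample leaves some pair
with no comparable sites or a saturated distance is redrawn (counted in
attribute `n_redraws`; more than 10× the replicate count aborts).

## The synthetic data generator

`simulate_dataset()` produces multilocus data sets with known species
structure so the whole pipeline can be validated end-to-end without any
sequence download.

* **Species tree** — topology by uniformly random sequential pair joins;
  the $n-1$ join events sit at equally spaced heights up to the root at
  `interspecific_depth` (units: expected substitutions/site). The tree is
  ultrametric and the two closest species are separated by at least
  $2\,\mathrm{depth}/(n-1)$. This models a set of *recognised, mutually
  divergent species* — a stylised radiation — rather than a population
  sample: a Kingman coalescent would routinely place sister species a
  vanishing distance apart, which contradicts the premise that the study
  taxa are distinct species.
* **Within-species structure** — each individual attaches to its species'
  ancestral lineage at a height drawn uniformly on
  `[0, intraspecific_depth]`, with a pendant branch equal to the
  attachment height (tips stay contemporaneous). One attachment is drawn
  per individual and shared across markers. When `intraspecific_depth` is
  well below the shallowest species split this behaves like a tight
  star around the species tip (conspecific divergence
  ≈ 2·max of two attachment heights); when it approaches the species-tree
  height, individuals attach *above* their species' origin and the
  genealogy scrambles — emulating unsorted ancestral polymorphism and
  introgressed individuals, the recognised causes of barcode failure in
  difficult genera. We adopted this over a pure star-from-tip model
  because a star can never break species monophyly: under a star,
  interspecific distances exceed intraspecific ones by construction
  (inter = intra + twice the split height), so "no species signal"
  control experiments would be impossible.
* **Substitution process** — the two-parameter (K80) model via its
  closed-form site transition probabilities, transition/transversion rate
  ratio `kappa` (default 2), total rate normalised so branch lengths are
  in expected substitutions/site. Per-marker `rate_multiplier`s scale all
  branches of that marker; the defaults (1.5, 1.0, 0.9, 0.6 for
  ITS/EF1a/RPB1/RPB2-like markers of 500 bp) reproduce the familiar
  ordering of a fast spacer down to a conservative polymerase subunit.
* **Indels** — with probability `indel_rate` per column, a single-column
  deletion event on one uniformly drawn species-tree lineage (all
  individuals of the descendant species get `-`). Columns remain
  homologous; there are no insertions. Default 0.
* **Defaults** — 20 species × 5 individuals, 4 × 500 bp markers,
  `interspecific_depth = 0.10`, `intraspecific_depth = 0.002`,
  `kappa = 2`. These are the package's reference design: strong but not
  trivial species signal (realised mean intraspecific K2P divergence
  ≈ 0.002–0.003, interspecific ≈ 0.1–0.25 depending on marker), sized so
  a full sweep runs in seconds.
* A `label_swap_fraction` contamination mode reassigns a fraction of
  species labels at random for negative-control experiments.

What the generator does **not** emulate: per-locus genealogies
(attachments are shared across markers, as for clonal or non-recombining
material), insertion events and alignment error, rate heterogeneity across
sites, base-composition bias, and any real population-genetic process
(mating systems, recombination, selection). Passing the recovery tests
therefore shows the *pipeline arithmetic* is sound under a controlled
truth, not that any particular real marker will discriminate real species.

## Numerical and reproducibility choices

* Percentages are rounded half-up to 2 decimals everywhere they are
  reported; raw distances are never rounded internally.
* All randomness derives from one integer seed through a documented
  integer mixing function (`barcodegap:::derive_seed`), with fixed stream
  ids per stage (species tree, per-marker evolution, attachments, label
  swaps, per-replicate bootstrap); rerunning any entry point with the same
  inputs and seed is byte-identical, which `scripts/acceptance.R` and the
  test suite verify on rendered output directories.
* Histogram bins are half-open `[lo, hi)` of width `bin_width` (default
  0.005 substitutions/site) from 0 to the maximum observed distance; the
  overlap interval `[min inter, max intra]` is reported only when the
  pooled distributions actually overlap.
* Sample identifiers must avoid Newick metacharacters; this is validated
  up front rather than quoted away, keeping the emitted trees portable.

## Problem sizes used by the shipped checks

The test suite and acceptance script validate at deliberately moderate
sizes: the reference design above (100 sequences × 2000 concatenated bp)
with 200 bootstrap replicates across ten seeds for the recovery and
degenerate controls; 100 random additive matrices of 5–12 taxa for NJ
consistency; 200 random 10-tip trees for the monophyly oracle; 1000
random transition/transversion count pairs for the K2P closed form. These
sizes give stable verdicts in a few minutes on one core; all of them are
plain function arguments and scale up freely.

## Known limitations

* Only p and K2P distances are offered — no JC69/TN93/GTR, codon-aware
  distances, or rate heterogeneity; the barcoding-gap literature this
  package serves reports K2P, and adding models would not change the
  evaluation logic.
* The NJ criterion scores strict species monophyly only; partially
  supported subclades within a non-monophyletic species are not credited.
* No alignment is performed or checked; inputs are trusted to be aligned,
  and ragged records are rejected rather than re-aligned.
* The PWG criterion with `singleton_policy = "count"` can report high
  rates for data sets dominated by singletons, since singletons only
  require a positive nearest-neighbour distance; the per-species records
  (`gap_records`) make the denominator composition explicit.
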