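---
title: "chromfold: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromfold: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromfold deconvolves a population-averaged Hi-C contact map for a single
genomic locus into an ensemble of single-cell 3D chromatin folds, and calls
specific pairwise and many-body (>= 3 bin) spatial interactions against a
random-polymer null. This vignette records the model, the tunable parameters
and the numerical decisions; empirical claims are limited to what the test
suite and `scripts/acceptance.R` themselves compute.

## The polymer model

A locus is a chain of beads, one per 5-KB bin, representing 11-nm chromatin
fiber. Geometry is set by four constants in `polymer_params()`:

* `bead_bp = 5000` — bp per bead.
* `fiber_diameter = 11` nm — hard-sphere excluded volume between non-bonded
  beads.
* `contact_threshold = 80` nm — two bins interact (are cross-linkable) when
  their beads are within this Euclidean distance.
* `bond_length = 30` nm — the fixed center-to-center step between
  consecutive beads. The literature fixes bead size, fiber width and the
  80-nm threshold but not a bond length; 30 nm is a single declared constant
  (roughly the fiber contour packed into a bead's footprint) and everything
  downstream is reproducible given it.

Chains are confined to a sphere preserving a constant nuclear base-pair
density: `radius = (3 L / (4 pi rho))^(1/3)` for a locus of `L` bp. The
density `rho` defaults to a 6.2-Gbp diploid genome in a 7-um nucleus
(~0.035 bp/nm^3; both are config, only the formula is fixed), giving
~151 nm for a 500-KB locus. No other energetics enter the model: the null
is uniform over confined self-avoiding chains.

## Chain growth and enrichment

`sample_null_ensemble()` grows all chains in lockstep. Each step screens 50
uniformly drawn directions against excluded volume, confinement and (for
constrained sampling) contact look-ahead, picks one survivor uniformly, and
adds `log(n_valid / n_candidates)` to a Rosenbluth-style log-weight, so
weighted averages target the uniform distribution over feasible chains.
Every 10 beads (and at the final bead) the population is systematically
resampled whenever the effective sample size falls below half the
population or any chain has dead-ended. The candidate count, checkpoint
interval and ESS rule are declared, tunable constants: the original
enrichment schedule lives in unpublished supplementary material, so this
standard sequential-Monte-Carlo schedule is an explicit stand-in. Its
correctness is not assumed: weighted contact frequencies are tested against
a rejection-sampling oracle (free growth, accept self-avoiding confined
chains) on short chains.

Constrained sampling (`sample_constrained_ensemble()`) enforces a set of
required contacts: a pair (i, j) prunes candidates for bead t < j that
could not reach bead i within `threshold + bond_length * (j - t)`, and bead
j itself must land within the threshold. Satisfaction is a hard guarantee,
not statistical; unsatisfiable states fail with an `InfeasibleState` error
after the restart budget (default 100).

## Calling specific contacts

Measured counts are quantile-normalized onto the null ensemble's
contact-frequency distribution (rank mapping over off-diagonal entries,
ties averaged), making measured and simulated values directly comparable.
The null over random contacts is a Bag of Little Bootstraps: each outer
replicate draws `n^0.7` chains without replacement (weight-proportional),
multinomially resamples to full size, and records contact frequencies. Two
views of the replicates are kept:

* per genomic distance, the resampled frequency of one uniformly drawn pair
  at that distance (the `NullDistribution` summary, one value per stratum
  per replicate);
* per pair, the add-one exceedance of that same pair's replicate
  frequencies, which is what `call_specific_contacts()` uses for p-values.

The same-pair reading keeps the test calibrated (pair-to-pair heterogeneity
from chain-end effects is not mistaken for signal) while retaining power
for moderate enrichments; both properties are asserted in the suite
(self-null call rate <= FDR, sensitivity >= 0.9 at 3x elevation). The
default replicate count is 10,000 — the reference setting — because the
add-one p-value floor `1/(1 + n_outer)` must undercut the
Benjamini-Hochberg threshold when true signals are sparse; 1,000 replicates
are enough for the per-distance summary but starve BH of resolution.
Pairs within two diagonals (10 KB) are never tested. Benjamini-Hochberg is
used for all multiple-testing control in the package (the variant is not
pinned down in the source literature).

Coarse-graining clusters the specific pairs in the 2D bin-index plane
(hierarchical, average linkage, Chebyshev metric), cuts the tree at
`round(0.05 * N)` clusters and keeps the minimum-p representative of each
(ties: larger normalized frequency, then lexicographic pair). The ~5%
retention is the published setting; the clustering algorithm itself is a
declared choice, frozen here.

## Knock-in perturbations and the dependency DAG

`knockin()` folds an ensemble constrained on one retained contact and
compares every pair's frequency to its own bootstrap null: significant
upregulation of contact k under knock-in of contact j yields a candidate
edge j -> k (one-sided, BH across all knock-in/target combinations).
Cycles — mutual upregulation is common between nested loops — are broken by
a frequency-ranked topological order: within a strongly connected
component only edges from the higher normalized Hi-C frequency to the
lower survive. Acyclic candidate sets are left untouched, so a genuine
long-loop -> nested-loop dependency is kept even when the nested loop has
the higher frequency.

Geometric infeasibility of contact combinations is screened by bound
propagation (`feasibility_precheck()`): shortest paths over exact bond
edges and <= threshold contact edges give distance upper bounds, and a
bound below the hard lower bound (bond length for adjacent beads, fiber
diameter otherwise) proves infeasibility. With an 80-nm ceiling and an
11-nm excluded volume, genuinely forbidden combinations require unusual
geometry (e.g. bond length above the threshold); `detect_infeasible()`
additionally flags subsets whose constrained sampling always dead-ends.
The orchestrated pipeline runs the cheap pre-check over pairs and triples
only; simulation-based detection is available but not the default, because
at default geometry it can only confirm feasibility at substantial cost.
Forbidden sets are closed under superset logically, never re-simulated.

## Deconvolution

The generative stand-in (the published model's exact likelihood is
supplementary and unavailable): each of `n_cells` cells carries a binary
state over the M retained contacts; the per-contact active counts follow
`Binomial(n_cells, f_j)` around the target frequency; the prior on a cell
adds, per active contact, base odds `logit(f_j)`, a `log(prior_boost)`
bonus when a DAG parent is active (default one nat), and a sparsity penalty
(default 0.1); states activating a forbidden subset have zero mass.
Systematic-scan Gibbs updates every (cell, contact) site from the full
conditional; correctness is checked against the exactly enumerated
posterior on an M = 2, 2-cell toy (chi-squared on 16 joint states, thinned
samples).

The pipeline sets the Gibbs target not to the normalized Hi-C frequency
`f` itself but to the background-corrected activation `(f - b) / (1 - b)`,
where `b` is the random-fold base rate of the pair: a population frequency
mixes cells where the contact is an active constraint with cells showing
it by chance, and folding cells at rate `f` would overshoot the measured
map. This correction is exact under that two-component mixture; it ignores
elevation of a pair caused by *other* active contacts (e.g. a nested pair
inside an active loop), which biases recovered activations upward for
strongly nested architectures — visible in `score_recovery()` on the
fixture and documented as a known limitation.

`n_cells` defaults follow the published arithmetic (25,000 polymers at ~50
folds per cell implies ~500 cells; the desk default is 200 cells at 10
folds). Burn-in 500 of 2,000 sweeps; the trace is returned for inspection.

## Many-body analysis

A k-body interaction is a clique of the 80-nm contact graph; 3-bodies are
exact triplets (not necessarily maximal, bitset-enumerated), maximal
complexes come from igraph's maximal-clique search with members >= 3.
Pairs closer than 2 bins are excluded from the graph — bonded-neighbour
triangles are ubiquitous and carry no information. For tallying across an
ensemble, 3-bodies are keyed by their exact member triplet and maximal
complexes by principal anchor pair plus size class (3, 4, 5, 6+): exact
member multisets of large cliques are too sparse to tally, and the
principal anchors (always the extreme members, since the genomic span of a
sorted member set is maximized at its ends) are the object of the
downstream landscape analysis anyway.

The stratified bootstrap null tallies complexes in a random ensemble and
resamples conformations for 1,000 replicates, stratified by (principal,
minor) span for 3-bodies and (size class, principal span) for maximal
complexes, at 5-KB granularity. Because a complex occurs at most once per
conformation, its bootstrap frequency distribution depends on its
occurrence count only; replicates are therefore drawn once per distinct
count (`Binomial(n, c/n)/n`) and pooled with class multiplicities —
distributionally identical to resampling every complex and orders of
magnitude cheaper. Empty strata encountered at calling time are pooled
within +/-2 span bins (reported per call); a complex with no null even
after pooling gets p = 1. Calibration (self-null specific rate <= 0.05) is
asserted in the suite. Conformations are treated as equally weighted in
many-body tallies; ensembles arrive resampled to near-uniform weights, so
the approximation is second-order.

Cluster concordance uses the coverage fraction (clusters containing all
members, or both anchors for principal loops), per-span medians for
specific versus non-specific complexes, and a label-permutation test
(1,000 replicates, add-one p).

## Enrichment classifier

Per-bin anchor-participation counts are sorted and the elbow located by
the maximum perpendicular distance to the chord between the first and last
sorted points (the published rule is shown only as a cartoon; this rule is
declared and unit-tested on hand geometry). Bins strictly above the elbow
are candidates; the top 20% of them are labeled enriched, the remainder
discarded as ambiguous, everything at or below the elbow not-enriched.
Profiles with the elbow at an end (constant or linear counts) are an
error rather than a silent empty set.

The classifier is a 500-tree random forest with per-tree balanced
bootstrap (equal positives and negatives per tree), grown to purity with
Gini splitting and sqrt(p) feature subsampling; class-balanced
(macro-averaged) out-of-bag error,
permutation (mean-decrease-accuracy) and Gini importances are computed
during training. No tree learner ships with the supported dependency set,
so the forest is implemented in compiled code inside the package; its
sanity battery (separable data -> OOB ~ 0, permuted labels -> OOB ~ 0.5,
planted features dominate both importance rankings, imbalance resistance)
is part of the suite. Cross-validated AUC fits the z-scoring on training
folds only.

## The synthetic world

`make_fixture()` states the test world once: 100 bins (500 KB), 12 planted
contacts arranged as 6 parent/child couples sharing a left anchor (each
couple implies a planted 3-body triple), parent activation 0.6, child 0.85
given an active parent and 0.15 otherwise, 200 cells, 10 folds per cell.
"Measured" counts are Poisson with depth 1000 at frequency 1 — deep
locus-level Hi-C at 5-KB resolution — over the truth ensemble's contact
frequencies. SPRITE-like clusters slice conformations at a 150-nm capture
radius with 0.7 subsampling, deliberately including indirect co-capture
(the co-capture assay cannot distinguish direct from indirect
cross-linking). Feature tracks give anchor bins +1.5 z-units on 3 of 8
tracks. The fixture does not emulate ligation artifacts, coverage bias or
genomic-distance-dependent noise; a green pipeline test therefore
establishes internal consistency of the method under its own generative
assumptions, not robustness to real-data artifacts.

## Degenerate inputs and tie-breaks

Constant measured matrices (quantile normalization), constant count
profiles (elbow), windows exceeding the locus half-length (boundary
strength), empty contact sets (overlap coefficient) and empty ensembles
(writers) are errors, not silent results. Ties: coarse-grain
representatives by p, then frequency, then pair order; principal anchors
lexicographic (automatic for sorted members); DAG orientation by
frequency rank with lexicographic pair fallback. Bootstrap exceedance is
`>=` with an add-one numerator and denominator, so p-values are never 0
and never exceed 1.

## Known limitations

* Spherical confinement only; no ellipsoid or lamina models, no
  chromatin-state energetics.
* The SMC schedule, the binomial deconvolution likelihood, the
  stratum-mean distance-corrected correlation ("SCC-lite": per-distance
  Pearson combined by pair-count weights, without the published method's
  smoothing) and the elbow rule are declared stand-ins for procedures
  whose exact published forms are unavailable.
* Background correction of Gibbs targets ignores cross-contact elevation
  (see Deconvolution).
* 3-body tallying is dense-coded and supports up to 270 bins per locus;
  larger loci need a coarser bin size or a larger `min_separation`.
* Mechanism-space averaging over DAGs is collapsed to the single inferred
  DAG.
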