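# chromfold

Population Hi-C measures the average contact frequency of chromatin bin
pairs over millions of cells; the single-cell 3D folds underneath are not
observed. `chromfold` deconvolves a balanced Hi-C contact map for one
genomic locus into an ensemble of single-cell chromatin conformations, and
from that ensemble calls *specific* (non-random) pairwise and many-body
(≥ 3 bin) spatial interactions. It is aimed at regulatory-genomics analyses
of super-enhancer loci: which enhancers, promoters and super-enhancers
co-locate in the same cells, in complexes of what order, and which chromatin
marks predict the hub regions.

## Model

A locus is a self-avoiding chain of beads (one per 5-KB bin, 11-nm fiber
diameter, 30-nm bonds) confined to a sphere that preserves constant nuclear
base-pair density; two bins are in contact when their beads lie within
80 nm. The pipeline:

1. **Null ensemble** — sequential Monte Carlo chain growth with
   checkpointed resampling produces a near-uniform ensemble of random
   confined folds; contact frequencies under this null give every pair
   `(i, j)` a genomic-distance-matched baseline.
2. **Specific contacts** — measured counts are quantile-normalized onto the
   null frequency scale; each pair's p-value is the add-one proportion of
   Bag-of-Little-Bootstraps replicate frequencies reaching its normalized
   value, with Benjamini–Hochberg control; a contact is specific when
   `q < 0.05`.
3. **Coarse-graining** — the specific set is clustered in the bin-index
   plane and ~5% minimum-p representatives are retained as the candidate
   driver set.
4. **Knock-in DAG** — for each retained contact, an ensemble constrained on
   that single contact reveals which other contacts it upregulates beyond
   the null; significant, cycle-broken edges form a directed acyclic
   dependency graph, and geometrically unsatisfiable combinations are
   flagged forbidden.
5. **Gibbs deconvolution** — binary per-cell contact states `s_c ∈ {0,1}^M`
   are sampled from a posterior combining a Binomial(`n_cells`, `f_j`)
   likelihood on per-contact active counts with a prior of base odds
   `logit(f_j)`, a parent-activation boost from the DAG, a sparsity
   penalty, and zero mass on forbidden subsets.
6. **Refolding** — every sampled cell state is folded into conformations
   that satisfy it exactly; the aggregated ensemble's *simulated Hi-C* is
   validated against the input (Pearson with the first two diagonals
   removed, plus a distance-corrected variant).

Downstream, many-body complexes are cliques of the 80-nm contact graph
(exact 3-bodies, or maximal complexes with principal/minor loop spans),
called specific against a stratified bootstrap null, summarised into
SE/E/P functional landscapes, checked for concordance with SPRITE-like
co-capture clusters, and fed into a balanced random-forest classifier that
predicts principal-loop-anchor enrichment from per-bin feature tracks.

A synthetic-fixture module (`make_fixture()`) generates complete test
worlds — planted contacts with a known dependency mechanism, ground-truth
cell states, folded truth ensembles, measured counts, annotations,
clusters and feature tracks — so the whole pipeline is testable offline.

## Worked example

```r
library(chromfold)

# a synthetic 300-KB locus with 4 planted loops, known single-cell truth
fx <- make_fixture(n_bins = 60, M = 4, n_cells = 100, folds_per_cell = 5,
                   seed = 42)
fx$pairs
#> # A tibble: 4 × 5
#>   contact     i     j role   couple
#>     <int> <dbl> <dbl> <chr>   <int>
#> 1       1     2    26 parent      1
#> 2       2     2     6 child       1
#> 3       3    32    55 parent      2
#> 4       4    32    37 child       2

pl <- deconvolve_pipeline(
  fx$measured_hic, fx$params,
  n_chains = 1000, n_outer = 5000, n_cells = 100,
  n_sweeps = 1000, burn_in = 300, folds_per_cell = 5, seed = 1
)
#> [chromfold] seed 1, locus chrS:0-300000 (60 bins)
#> [chromfold] 162 of 1653 tested pairs specific at FDR 0.05
#> [chromfold] 8 coarse-grained contacts
#> [chromfold] dependency DAG: 13 edges, 0 forbidden subsets
#> [chromfold] simulated-vs-normalized Hi-C Pearson (excl. 2 diagonals): 0.9601
```

162 of the 1653 testable pairs rise above the random-polymer null; the 8
retained representatives include the planted loops and their
neighbourhoods, and knock-in simulations recover 13 dependency edges.
The deconvolved per-contact activation marginals track the
background-corrected targets:

```r
tidy(pl$fit)
#> # A tibble: 8 × 3
#>   contact target_frequency marginal
#>     <int>            <dbl>    <dbl>
#> 1       1            1.000     1
#> 2       2            0.573     0.7
#> 3       3            0.313     0.37
#> 4       4            0.115     0.18
#> ...
```

and the refolded ensemble reproduces the fixture's target map:

```r
score_recovery(fx, calls = pl$calls, sim_hic = pl$sim_hic)
#> # A tibble: 3 × 3
#>   stage           metric        value
#>   <chr>           <chr>         <dbl>
#> 1 contact_calling recall        0.75
#> 2 contact_calling precision     0.253
#> 3 reconstruction  pearson_excl2 0.967

hic_pearson(pl$sim_hic, fx$target_hic, exclude_diagonals = 2)
#> [1] 0.9673117
```

The Pearson correlation of 0.967 (first two diagonals excluded) says the
aggregate contact frequencies of the reconstructed single-cell folds match
the ground-truth map; recall/precision describe how the specific-contact
caller relates to the planted loops (neighbouring pairs of a real loop are
genuinely elevated, hence the modest exact-pair precision).

Result tables are tibbles with `tidy()`/`glance()` methods and `autoplot()`
visualisations (`autoplot(pl$hic_norm)`, `autoplot(pl$calls)`,
`autoplot(pl$fit)`, …). A thin command-line wrapper over these functions is
installed at `inst/cli/chromfold.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's two headline quantities
from scratch against the installed package: the percentage of specific
contacts retained by default coarse-graining (300 synthetic calls on a
100-bin locus), and the simulated-vs-target Hi-C Pearson correlation (two
diagonals excluded) of the full pipeline on the desk-scale fixture
(100 bins, 12 planted contacts, 200 cells, 2000-chain ensembles, 2000
Gibbs sweeps, 10 folds per cell). Run from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The vignette (`vignettes/chromfold-methods.Rmd`) documents the model
assumptions, every tunable constant, and the numerical and design
decisions in detail.
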