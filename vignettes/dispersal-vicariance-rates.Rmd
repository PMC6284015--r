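---
title: "Dispersal and vicariance rates from adjacency-constrained range models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal and vicariance rates from adjacency-constrained range models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangaea)
```

## The problem

Fossil phylogenies of late Paleozoic tetrapods span the assembly of Pangaea,
a time when mountain belts, inland seaways and climatic zonation repeatedly
rearranged the barriers between land faunas.  Two signatures of such barriers
are legible in a time-calibrated phylogeny whose tips carry geographic
ranges: *vicariance* (an ancestral range split between the two daughters of a
node) and a change in the rate of *anagenetic dispersal* (range expansion
along a branch).  `pangaea` estimates both as explicit rates through
geological time: events per million years in half-stage time bins, corrected
by a tree-shape null model, with standard-error bands, for the whole tree and
for named clades.

The pipeline has four statistical layers, each usable on its own:

1. a likelihood model of geographic range evolution on the tree
   (dispersal--extinction anagenesis plus a cladogenetic event table), fitted
   by maximum likelihood and compared across cladogenesis rule sets by AIC;
2. biogeographic stochastic mapping: sampling complete timed histories of
   ranges and events consistent with the fitted model *and* the tip data;
3. a forward-simulation null model on the same tree: histories evolved from a
   random root range under the same fitted rates, ignoring the tip data;
4. rate curves: events binned in half-stages, divided by bin duration,
   averaged over maps, with the null mean subtracted.

## The range model

### State space

Geographic state is a non-empty subset ("range") of a fixed list of areas.
Two constraints cut the power set down: a cap on range size
(`max_range_size`, default 4; tests and examples here mostly use 2), and —
by default — adjacency-connectivity: a range must be connected in the
area-adjacency graph.  The connectivity constraint is this package's own
design choice: a terrestrial range split across a barrier is not a coherent
dispersal unit at continental scale, and it keeps the 13-area state space
small.  It can be switched off (`connected_only = FALSE`).

Ranges are encoded as bitmasks; `build_state_space()` enumerates the
permitted set deterministically (by size, then bit pattern), so state indices
are reproducible.

### Anagenesis

Along a branch, ranges evolve by a continuous-time Markov chain with two
parameters, both in events per lineage-Myr:

* **dispersal `d`** — range `R` gains an area `a` at rate
  `d × |{b ∈ R : b adjacent to a}|`, provided `R ∪ {a}` is itself permitted.
  Scaling by the number of occupied source areas is the standard DEC
  convention.
* **local extinction `e`** — `R` loses each occupied area at rate `e`; a
  single-area range decays into an explicit absorbing null (empty) range.

The generator is built densely (`anagenetic_generator()`); transition
probabilities come from the matrix exponential.  Because one fit evaluates
`expm(Q t)` for hundreds of branch lengths on one small `Q`, the propagator
diagonalises `Q` once and reuses the eigendecomposition, falling back to
`Matrix::expm` (scaling and squaring) whenever the eigenvector matrix is
ill-conditioned (condition-number guard at 1e8).  Round-off negatives are
clipped and rows renormalised; the two routes agree to well below the 1e-8
tolerances used in the tests.

### Cladogenesis

At a node the ancestor range is partitioned between the daughters according
to one of three rule sets (`cladogenesis_table()`), each a proper
distribution over ordered daughter pairs with equal weights within a rule
set:

* **DIVA-like** — single-area ancestors are copied to both daughters;
  wider ranges undergo vicariance *only*: every ordered split into two
  disjoint, non-empty, permitted subsets of any sizes.
* **DEC-like** — single-area sympatry; for wider ranges, subset sympatry
  (one daughter is one area of the range, the other keeps the whole range)
  plus vicariance restricted to splits with a single-area daughter.
* **BAYAREA-like** — both daughters copy the ancestor exactly; no range
  change at nodes.

Two hard rules hold in every variant: vicariance is impossible for
single-area ancestors (a region cannot be subdivided), and no daughter range
outside the permitted space is ever produced.  There is deliberately **no
founder/jump parameter**: on a supercontinent the only routes are via
adjacent areas, and a jump process would also bias inference toward
cladogenetic over anagenetic dispersal.  The "-like" suffixes signal that
the rule sets are pinned here, in code and tests, rather than inherited from
any external implementation.

### Likelihood, fitting, model choice

`biogeo_loglik()` runs Felsenstein pruning with cladogenetic mixing at nodes
and a flat prior over permitted ranges at the root (configurable in
principle; flat is the neutral default when nothing is known about the root).
`fit_ml()` maximises over `(d, e)` on the log scale with multi-start
L-BFGS-B (three spread starts by default, box `[1e-6, 10]`).  `select_model()`
compares variants by `AIC = 2k − 2 lnL` with `k = 2` throughout; exact ties
are reported, never silently broken.  `ancestral_marginals()` adds the
standard up–down pass; both the likelihood and the marginals are tested
against brute-force enumeration over all ancestral assignments on small
trees (rel. tol 1e-8).

## Stochastic mapping

`sample_history()` draws a complete history in three steps: (i) the root
range from its posterior; (ii) at each node, a cladogenetic outcome and the
daughter branch-top ranges, conditionally on the data below (root-to-tip
*joint* sampling — drawing each node independently from its marginal would
produce inconsistent parent–child pairs, so the joint scheme is the default
and the independent one is available only behind
`sample_node_ranges(method = "independent")` for sensitivity checks); (iii)
an endpoint-conditioned anagenetic path along every branch by
uniformization: the jump count is drawn exactly from its conditional
distribution (accumulating Poisson × `R^n` terms, cap 10,000), the jump
chain is bridged, virtual jumps are discarded, and jump times are uniform
order statistics.  Across repeated draws the node-range frequencies converge
to the marginal table — that consistency is asserted within 3 binomial
standard errors in the tests.

Every sampled history passes a structural validator
(`validate_history()`): dispersals gain exactly one area adjacent to the
occupied range, losses drop exactly one area, no vicariance at single-area
ancestors, all events inside the tree's span, and each branch path replays
exactly from the parent's daughter range to the child's range.

## The null model

`simulate_null_history()` evolves a history forward over the *same* tree
under the *same* fitted rates and event table, but unanchored to the tips:
the root range is uniform over the permitted space (uniform over single
areas is available, since "a random starting range" admits both readings),
anagenesis runs by Gillespie simulation, and each node draws from the
cladogenesis table.  Null and data-conditioned histories share one validator
and one event-counting path, so no code fork can bias the subtraction.

If a lineage loses its last area, the default policy re-seeds it into a
random area adjacent to the lost one, recorded as a `reseed` event that
never enters the rate curves; this keeps the ensemble size fixed.  The
alternative (`extinct = "discard"`) restarts the history, which is only
practical on small trees — on a large tree some lineage almost surely dies.

## Rates

`bin_events()` counts dispersal and vicariance events per half-stage bin
(cladogenetic bookkeeping kinds — sympatry, subset sympatry, range copy —
and reseeds are excluded); `counts_to_rates()` divides by bin duration;
`aggregate_series()` averages over mapping iterations, attaches the standard
error of the mean, and subtracts the null mean.  Negative corrected rates
are meaningful (fewer events than the tree shape alone would generate) and
are never clipped.  Two SE modes exist because the iteration structure is
nested (maps within trees): `"pooled"` (default; SD across all iterations)
and `"per_tree"` (SD across per-tree means).  `clade_series()` restricts
events to a clade's subtree — the clade's subtending stem branch is outside
— and applies the identical filter to the null.

Time bins are informal substages: each international stage split at its
midpoint (`make_substage_bins()`).  Bin assignment is half-open with the
older edge inclusive, and the youngest bin also keeps its younger edge, so
the bins partition the closed study window; out-of-window events are dropped
with a warning, never silently.  Stage boundaries ship as an editable CSV
(ICS chart v2023/06 ages for the Carboniferous and Permian) because
chronostratigraphic boundary ages drift between chart editions.

## Calibration and tree handling

The pipeline consumes time-calibrated trees and replicates them to propagate
age and topology uncertainty: random polytomy resolution (uniform over the
`(2k−3)!!` rooted local resolutions, by sequential random insertion), tip
ages drawn uniformly within stratigraphic intervals, then minimum-age node
dating — each node its oldest child plus `min_branch` (default 0.1 Myr; the
value only needs to keep branch durations positive) — under a root maximum
(409.4 Ma for the tetrapod analyses, the molecular-clock age of the
tetrapod–lungfish split).  This deliberately simple calibrator replaces
outgroup-based probabilistic node dating: the downstream inference consumes
only calibrated trees, and the replicate design (many trees, many maps) is
what matters for the rate curves.  Tips whose first appearance postdates the
study window are kept during calibration (their ghost lineages inform node
ages) and dropped before the biogeographic analysis.  `time_slice()`
implements taxon filtering for time-sliced analyses with ghost lineages
included: a tip is kept if its observed range *or* its subtending branch
interval crosses the slice.

## Supertree utilities

`encode_mrp()` codes each internal node of each rooted source tree as a
binary character (members 1, others 0, absent taxa "?"); root nodes are
skipped because their all-ones columns cannot affect tree length.
`exact_parsimony()` is a desk-scale exact search: it enumerates all rooted
topologies (refusing more than `max_taxa = 9` taxa) and scores them with
Fitch parsimony, with rooting made informative by a hypothetical all-zero
outgroup — absence is the ancestral state in MRP coding.  All minimal trees
are returned; ties are never broken.  Full-scale matrices are exported to
NEXUS or TNT format for external heuristic search programs;
`strict_consensus()` summarises their results.

## The synthetic-data generator

`simulate_fossil_tree()` grows a birth–death tree forward from one lineage
at the older window edge, keeping extinct tips (fossils) and conditioning on
the exact requested tip count by rejection.  Defaults (`sim_config()`):
50 tips, birth 0.09 and death 0.045 per lineage-Myr, window 330–260 Ma — a
Carboniferous–Permian-scale window with realistic turnover, sized so the
full test suite runs in minutes.  Stratigraphic intervals are the true tip
ages ± up to 2 Myr of uniform jitter (a typical stage-level dating
uncertainty).  `simulate_tip_ranges()` simulates ranges forward under the
model — by construction the same mechanism as the null simulator — and
returns the full true history, so parameter recovery and null calibration
can be scored against ground truth.  `pangaea_fixture()` supplies the
13-region Pangaea adjacency layout; it is a documented reconstruction (Hueco
seaway barrier between the North American regions, an eastern North
America–western Europe connection, the Cathaysian Bridge linking eastern
Asia to India and Australia), with the Gondwanan interior contacts filled in
from conventional plate reconstructions, and is labelled approximate — it is
not anyone's published matrix.

What the generator does *not* emulate: geographically biased fossil
sampling, range-dependent diversification, time-varying rates or barriers,
and any coupling between range loss and lineage death.  Passing tests
therefore demonstrate internal correctness and calibration of the method,
not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Propagator: eigendecomposition with conditioning guard, `Matrix::expm`
  fallback; negative round-off clipped; `t = 0` returns the identity.
* Uniformization: exact jump-count draw; the bridge errors loudly if the
  endpoints have zero transition probability (which indicates an upstream
  sampling bug, not data trouble).
* Optimiser: log-scale L-BFGS-B, three starts, convergence code surfaced on
  the fit object; an error carries the best value found if every start
  fails.
* Zero-length branches are legal (identity transition); equal-endpoint
  zero-length paths are empty.
* A stage table must be contiguous and strictly ordered; violations are
  validation errors, not warnings.
* All randomness flows from explicit integer seeds; nested designs derive
  per-replicate sub-seeds (`< 2^31`) from the one top-level seed, so a whole
  pipeline is bit-reproducible from its config.

## Problem sizes used in the checks

The shipped tests exercise: exhaustive likelihood grids on 2–4-tip trees
with 2–3 areas; 2,000-draw mapping-consistency checks on a 3-tip fixture;
1,000 + 1,000 history validator sweeps on a 50-tip tree over the 13-area
layout; parameter recovery on twenty 200-tip trees (d = 0.02, e = 0.01);
ten replicate 5-tree × 5-map × 5-null calibration pipelines on 25-tip trees;
and MRP self-consistency on twenty compatible source-tree sets of 6–7 taxa.
These sizes are the package's own trade-off between statistical resolution
and a test suite that completes in minutes.

## Known limitations

* **The local-extinction rate is weakly identified.**  With tip data
  simulated forward under the model (re-seed policy), the likelihood's
  absorbing null range charges every surviving single-area lineage a
  survival penalty `exp(−e·t)` that the generator never imposes, so `ê`
  collapses toward zero while `d̂` recovers well.  This mirrors the
  well-known behaviour of DEC-type models on empirical data, where `ê ≈ 0`
  is the norm.  Dispersal rates, vicariance rates and model choice are
  insensitive to this; absolute extinction-rate estimates should not be
  interpreted.
* The null subtraction is calibrated *across* replicate analyses: within a
  single analysis all maps condition on one data set, so the
  mapping-iteration SE understates between-data-set variance.  The
  calibration test accordingly checks that corrected rates are centred on
  zero across replicate pipelines.
* The adjacency matrix is static through time; analyses over windows where
  barriers changed should be run as separate time slices
  (`run_region_rerun()` supports truncation and alternative region
  systems).
* Exact parsimony is factorial and capped at 9 taxa by design; large
  matrices go to external search software via the exporters.
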