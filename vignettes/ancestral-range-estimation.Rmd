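---
title: "Ancestral range estimation with decrange: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral range estimation with decrange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decrange)
```

# The inference problem

Given a fossil-dated, ultrametric phylogeny (a *chronogram*, branch
lengths in millions of years) and a coding of each extant taxon to one or
more biogeographic areas, we want the probability distribution of the
geographic range at every ancestral node, plus a defensible choice among
competing models of range evolution.  The package was built around a
five-area system used for tarantula biogeography — A = Indian
Subcontinent, B = non-Indian Indomalaya, C = East of the Wallace Line,
D = Americas, E = Africa — but any 2–16 single-letter area system works.

Branch lengths are always absolute time in Ma; no unit inference is
attempted, because all rates below are *per Ma*.

# The DEC model family

A geographic range is a non-empty subset of the areas.  The state space
(`build_state_space()`) is every subset of cardinality at most
`max_range_size`, minus an explicit exclusion list of biogeographically
implausible combinations (for the tarantula system, combinations such as
Asia + Americas that skip intervening realms).  Exclusions remove exactly
the listed subsets — supersets must be listed explicitly — and excluded
states are removed from the space altogether (no rows or columns in the
rate matrix), rather than rate-zeroed.  The null (empty) range is kept in
the space by default: it is the absorbing end point of extinction and
keeps the rate matrix well formed, but it is assigned zero probability at
tips and at the root.

**Anagenesis.**  Along a branch, a range `S` gains an unoccupied area `a`
at rate `d * |S|` — every occupied area is an equally good dispersal
source; there is no distance scaling — and loses an occupied area at rate
`e` per area.  A singleton decays to the null range at rate `e`.  These
rules define the generator returned by `build_rate_matrix()`; branch
transition probabilities are its matrix exponential.

**Cladogenesis.**  At a speciation node the parent range is partitioned
between the daughters according to the family
(`clado_distribution()`):

* **DEC** — a singleton parent is copied to both daughters (sympatry); a
  widespread parent either passes a single area to one daughter and its
  full range to the other (subset sympatry), or splits with one daughter
  receiving a single area and the other the remainder (classic
  vicariance).
* **DIVALIKE** — vicariance by *any* disjoint bipartition, plus sympatry
  for singletons.
* **BAYAREALIKE** — both daughters copy the parent range.
* **+J** — any family may add founder-event speciation: one daughter
  keeps the parent range while the other instantaneously colonizes a
  single unoccupied area.

Every distinct non-jump scenario carries base weight 1 and every jump
scenario carries weight `j` (bounded to `[0, 3]`); weights are normalized
per parent state.  With two areas this reproduces the familiar six
equiprobable outcomes for an `AB` parent under DEC.  Scenarios whose
daughters fall outside the allowed state space are dropped before
normalization, so exclusions constrain cladogenesis and anagenesis
consistently.

**Likelihood.**  `dec_loglik()` runs Felsenstein pruning over the range
states: indicator vectors at the tips, matrix-exponential updates along
branches, scenario-table convolution at nodes, with per-node rescaling
against underflow.  The root convention is a uniform weighting of the
root conditional likelihoods over all allowed non-null states, with no
cladogenesis event above the root; a `"conditional"` option fixes the
root state instead, which is useful for degenerate checks and for the
simulator cross-validation.  The published analyses this package mirrors
do not document their root convention, so both are exposed and small
log-likelihood offsets against other implementations should be expected.

`fit_ml()` maximizes over `(d, e)` — and `j` when requested — with
bounded L-BFGS-B on log-transformed rates from a deterministic grid of
starting points (five by default).  `k` is 2 or 3 accordingly, and the
AICc sample size `n` is the number of coded tips: that value is not
stated by the source analysis but is the only choice consistent with its
printed AICc column (with `n = 29`, all six published AICc values are
reproduced to printed precision).

**Reconstruction.**  `ancestral_marginals()` adds the standard outside
(up) pass, giving each node's marginal posterior over ranges given all
tip data; the state at a node is the range of the lineage immediately
before it speciates.  `count_events()` turns a fitted model into per-node
event counts by stochastic mapping: it samples the parent's state, the
parent's cladogenetic scenario, an endpoint-conditioned anagenetic
history along the focal branch (by uniformization), and the focal node's
own scenario, all conditioned on the tip data.  Anagenetic gains count as
dispersal, losses as extinction, vicariant scenarios as vicariance, and
jumps as dispersal.  The counting window is deliberately "the focal
node's cladogenesis plus its subtending branch": published per-node
event matrices (e.g. one vicariance plus two dispersals explaining a
trans-Atlantic split) are most naturally read over that window.  A
`"clado"`-only window is available.  Modal counts over the maps mirror
the integer event matrices of the literature; means are reported
alongside.

# Model comparison

`aicc()`, `akaike_weights()` and `lrt_plus_j()` implement the standard
small-sample information criterion, its weights (computed after
subtracting the minimum, so extreme spreads cannot overflow), and the
one-degree-of-freedom chi-square likelihood-ratio test for the nested
base/+J pairs.  `compare_models()` assembles the six-model table and
flags pairs significant at `alpha = 0.05` — the conventional level, and
the one consistent with the published conclusion that DEC and DEC+J do
not differ significantly while the DIVALIKE and BAYAREALIKE pairs do.
Whether published asterisks derive from an LRT or an AICc rule is not
documented; both the LRT p-value and the AICc difference are in the
table, and the flag follows the LRT.

# Bayesian binary reconstruction (BBM)

As an independent second method, each area's presence/absence is treated
as a two-state symmetric (binary JC) character with transition
probability `P(same) = 1/2 + 1/2 exp(-2 r t)` and stationary root prior.
`run_bbm()` samples internal node states by Gibbs sweeps and the
per-character rate by Metropolis steps on the log scale under a
log-uniform prior, across several independent chains; presence
probabilities are pooled over post-burn-in samples.  The default burn-in
is 10%, the only burn-in figure the source analysis reports.  The
published run configuration (1 M generations, 10 chains, sampling every
100) ships as the `"study"` preset; the `"desk"` default (10 k
generations) exists because the sampler mixes in seconds on desk-scale
trees.  Because the areas are sampled independently, a composite range
distribution per node is assembled explicitly: the product of per-area
marginals, restricted to the allowed states, with the all-absent
combination excluded and the rest renormalized.  This composition rule
is not documented by the reference implementation of BBM, so it is
stated here and numeric parity with published per-node posteriors is not
promised.  A split-chain diagnostic flags runs where the first and
second halves of the chains disagree by more than 0.1 at any node.

# Synthetic data

All tests run on synthetic data; nothing is downloaded.

* `simulate_chronogram()` is an explicit Yule sampler conditioned on the
  tip count: with `k` lineages the next speciation waits
  `Exp(k * birth_rate)`, a uniformly chosen lineage splits, and a final
  exponential interval closes the tree, which is then rescaled to a
  120 Ma root age by default — the age scale of the deepest tarantula
  divergences.  The explicit construction makes the waiting-time
  distribution itself a testable property.
* `simulate_ranges()` is the exact generative counterpart of the
  likelihood: uniform singleton root, Gillespie simulation of the
  anagenetic CTMC along branches, scenario draws at nodes, with true
  node states and per-branch event counts recorded.  A branch history
  absorbed into the null range is redrawn (and counted): whole-tree
  rejection cannot terminate at realistic sizes (a 300-tip, 120 Ma tree
  at `e = 0.01` expects ~30 null absorptions), and branch-wise
  conditioning is the generative match to a pruning likelihood in which
  null histories contribute zero.  For parameter-recovery experiments
  the cleaner design — used throughout the tests — is a state space
  built with `include_null = FALSE` for both the generator and the fit,
  which removes the conditioning question entirely; fitting the
  null-inclusive likelihood to survival-conditioned data visibly biases
  `e` downward, which is worth knowing before interpreting real fits.
* `simulate_discordant_genetrees()` (random NNI moves plus random taxon
  deletion) and `simulate_codon_alignment()` (equal-rates simulation
  with an elevated third-position rate) provide fixtures for the
  gene-tree congruence filter and the saturation-stripping step.

What the generators do *not* emulate: extinct lineages, among-lineage
rate variation, distance-dependent dispersal, gene-tree discordance from
coalescent processes rather than estimation error, and alignment error.
A pipeline passing all tests here is validated as *software* on its own
model class; that is a statement about correctness, not about the
realism of DEC-type models for any particular clade.

# Supermatrix filters

The matrix-construction stages mirror a stringent "core ortholog"
workflow: `occupancy_filter()` keeps only ortholog groups present in
*all* required taxa; `filter_by_rf()` scores each gene tree against a
reference topology by Robinson–Foulds distance on their shared taxa
(unrooted, branch lengths ignored, non-trivial bipartitions only) and
discards scores at or above 6; `strip_third_positions()` removes every
third alignment column of a codon-aligned matrix — columns, not ungapped
sequence positions, because codon-aware alignment keeps columns in
triplets; `concatenate_alignments()` builds the partitioned supermatrix,
filling missing blocks with `?`.  Completeness counts only unambiguous
`A/C/G/T` cells as present (`N`, `-`, `?` are missing): one defensible
reading of a "percent complete" matrix descriptor, applied consistently.
Upstream steps (assembly, orthology search, alignment, trimming) are out
of scope; the pipeline accepts pre-trimmed alignments.

# Numerical choices

* Matrix exponentials: dense scaling-and-squaring (`arma::expmat`) on
  state spaces of at most 32 states; no sparse machinery at desk scale.
* Pruning is rescaled per node; likelihoods are exact in log space down
  to hundreds of tips.
* Ultrametricity is validated against the *median* root-to-tip depth
  with a relative tolerance (default `1e-6` of tree height), so the
  offending tip — not its well-behaved siblings — is named, and
  supplementary trees with rounding noise pass with a looser tolerance.
* Optimizer: five deterministic starts, `d, e` bounded to
  `[1e-7, 10]` per Ma, `j` to `[0, 3]`.  Non-convergence after all
  starts is flagged on the result, not thrown.
* Uniformization handles endpoint-conditioned path sampling; the jump
  count distribution is truncated when the cumulative Poisson mass is
  within `1e-12` of 1.

# Problem sizes used by the test suite

The suite validates the likelihood engine against brute-force history
enumeration on instances of up to 4 tips and 3 areas (tolerance `1e-8`;
`+J` with `j = 0` matches the base model to `1e-12`), recovers
`d = 0.02, e = 0.01` from 20 replicates of 300-tip simulations with
median relative error under 25%, detects founder events by LRT in at
least 8 of 10 replicates simulated at `d = e = 0.005, j = 1.5` on
100-tip trees, and checks the BBM sampler against exact two-state
marginals on 5-tip instances to within 0.02.  These sizes were chosen as
the smallest that make the statistical assertions stable.

# Known limitations

* No time-stratified or distance-scaled dispersal matrices.
* Polytomies are readable but the likelihood engine requires a binary
  tree; resolve them upstream.
* `e` is weakly identified from extant ranges alone; expect wide
  intervals and downward bias under survival-conditioned data.
* BBM composite ranges are a documented construction, not a replication
  of any particular program's internals.
* Replicating the published tarantula numbers exactly requires the
  study's supplementary chronogram, codings and exclusion list (see
  `inst/extdata/replication/README.txt`); without them the replication
  check reports failure rather than silently passing.

# A worked example

```{r example, eval = FALSE}
ps <- study_preset()                       # 29 tips, 5 areas, 120 Ma
sp <- build_state_space(ps$areas, ps$max_range_size, ps$exclusions,
                        include_null = FALSE)
tree <- simulate_chronogram(ps$n_tips, root_age = ps$root_age, seed = 1)
truth <- dec_params(0.015, 0.005, j = 0.3, family = "DEC", jump = TRUE)
sim <- simulate_ranges(tree, truth, sp, seed = 2)

mt <- model_test(tree, sim$tip_ranges, sp, n_starts = 2)
mt$table[, c("model", "loglik", "aicc", "weight", "significant")]

fit <- mt$fits[["DEC+J"]]
marg <- ancestral_marginals(tree, sim$tip_ranges, fit$params, sp)
head(map_states(marg), 3)

count_events(tree, sim$tip_ranges, fit$params, sp,
             node = ps$n_tips + 2L, n_maps = 200, seed = 3)
```
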