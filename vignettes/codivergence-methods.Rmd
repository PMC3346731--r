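---
title: "Testing codivergence between mimetic radiations: methods and design"
author: "comimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing codivergence between mimetic radiations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comimic)
```

# The question

Müllerian co-mimics — pairs of unpalatable species that share a warning
pattern — are expected to exert reciprocal selection on one another. If that
selection has shaped their diversification, the phylogenies of the two
radiations should be *codivergent*: topologically congruent (matching
branching patterns among associated populations) and temporally congruent
(matching divergence times). `comimic` implements the machinery needed to
test this for the classic case of *Heliconius erato* (treated as the model,
being the more abundant partner) and *H. melpomene* (the mimic): event-based
cophylogeny mapping, Monte-Carlo significance tests of congruence, a
distance-based correlation test, coalescent population-tree inference by
minimising deep coalescences, and the population-genetic statistics used to
argue that a lower within-species diversity reflects a smaller effective
population size rather than a younger radiation.

# Event-based reconciliation

## Model

The mimic tree is mapped onto the model tree by assigning every internal
mimic divergence a position on the model tree and one of three events:

* **codivergence** — the mimic divergence tracks a model divergence; the two
  daughter lineages follow the model node's two daughter subtrees;
* **duplication** — the mimic diverges while remaining on a single model
  lineage; both daughters stay within that model subtree;
* **switch** — a duplication one of whose daughters colonises a
  *non-ancestral* model lineage (colonising an ancestor would be a
  time-travelling association). A switch node is charged
  `cost_duplication + cost_switch` and counts in both the duplication and
  switch tallies, reflecting that it is a duplication followed by a model
  switch.

In addition, one **loss** is charged for every internal model node that a
mimic lineage passes through without diverging (the mimic is absent from one
of the model's daughter lineages where its history predicts presence).
Losses attach to mimic edges, not nodes. The default cost regime is
`(codivergence, duplication, switch, loss) = (0, 1, 1, 2)`, the standard
regime for event-based cophylogeny mapping; under it, minimum cost 0 is
attained exactly when the association induces an isomorphism between the
mimic tree and the induced model subtree.

## Algorithm and numerical choices

`reconcile_min_cost()` runs a dynamic programme over mimic-postorder × model
positions. For each mimic node `p` and model position `h` it computes the
cheapest embedding of `p`'s subtree with `p`'s event exactly at `h`, using an
"entry" table that lets a daughter lineage descend from its entry point with
one loss per internal model node passed. Switch targets are any position
outside `h` and its strict ancestors; the switching daughter's next event
happens exactly at its landing site (descending after a landing is never
cheaper than landing deeper directly). The total is minimised over root
placements, with no loss charged above the mimic root's placement — the
mimic clade originates where it is placed.

Design points worth stating explicitly:

* **Timing of switches.** Switch targets are unconstrained by divergence
  times inside the dynamic programme; this untimed formulation is exactly
  checkable against brute-force enumeration, which the test suite does on
  hundreds of random instances (≤ 5 leaves, where enumeration over all
  assignments of internal mimic nodes to model positions is feasible). A
  cost-only C++ implementation backs the Monte-Carlo loops and is asserted
  equal to the R implementation and to the enumeration.
* **Co-optimal enumeration.** All minimum-cost solutions are recovered by
  backtracking, deduplicated, ordered lexicographically by their event
  string, and capped (default 100) for reproducibility.
* **Polytomies** are rejected by the dynamic programme (the analyses assume
  resolved trees); `resolve_polytomies()` offers a deterministic arbitrary
  resolution and flags its output.
* **Ties.** Costs are compared with an absolute tolerance of 1e-9 when
  collecting co-optima; with the default integer regime ties are exact.

## The worked example

`heliconius_country_example()` carries 12-leaf country-level population
trees for the two species and the 12 mimicry associations. The topologies
are a transcription from a textual description of MDC country-level
phylogenies (the machine-readable originals are not distributed); the few
internal arrangements the description leaves open were fixed once, before
any testing, to the variants that keep the described clade structure. On
this pair the minimum cost is 8, attained by a single reconciliation with 9
codivergences (of a possible 11), 2 duplications whose daughters switch —
one colonising the East-Ecuador *etylus* model population, one the Trinidad
*hydara* population — and 2 losses, one at the ancestor of the Panama and
Trinidad *hydara* populations. The published account of this reconstruction
reports 8 codivergences, the same 2 duplication-with-switch events and only
the *hydara* loss; those 10 events cannot account for all 11 divergences of
a fully resolved 12-leaf mimic tree, so the transcription necessarily adds
one codivergence and the loss its placement implies. The two accounts agree
on every event the published narrative names.

# Congruence tests

Three Monte-Carlo tests are provided, each returning the observed statistic,
the raw proportion p, and a two-sided Wilson 95% upper bound on p
(`wilson_upper()`, z = 1.959964). p-values are raw proportions — they can be
exactly 0 — with the `(r+1)/(n+1)` correction available behind a flag.

1. **Random associations** (`mc_test_random_associations()`): permutes the
   model column of the association pairs; p is the fraction of null minimum
   costs ≤ the observed minimum.
2. **Random mimic tree** (`mc_test_random_mimic_tree()`): regenerates the
   mimic topology on the same leaves under a Yule null (random sequential
   joins; a uniform/PDA null is the alternative), keeping associations
   fixed. This null respects the unequal probabilities of tree shapes.
3. **Distance correlation** (`distance_correlation_test()`): for a focus
   node, Spearman's rank correlation (average ranks on ties) between mimic
   and model leaf-pair distances over the association pairs in the focus
   subtree, against a null that permutes mimic leaf labels within the
   subtree. Patristic distances are used when both trees carry branch
   lengths, nodal (edge-count) distances otherwise, and the choice is
   reported. Nodes with fewer than four association pairs are reported as
   not evaluable rather than tested; zero variance in either distance
   vector flags the statistic as undefined.

Permuting labels within the focus subtree (rather than regenerating its
topology) is the narrower null: it conditions on both tree shapes and asks
only whether the *matching* of leaves is exchangeable.

## Calibration

With independent Yule mimic trees, the minimum-cost tests are slightly
conservative at small leaf counts: minimum costs are small integers, the
observed value often ties many null replicates, and ties count against
rejection. Measured over 500 simulations (8 leaves, 199 replicates), the
type-I error at α = 0.05 is about 0.02–0.035 for the cost-based tests and
about 0.05 for the distance-correlation test. The tests are valid (never
anti-conservative); the discreteness is intrinsic to cost-based Monte-Carlo
tests at this problem size. On pure-codivergence pairs of 8–12 leaves all
three tests reject at α = 0.05 in essentially every simulation.

The printed Wilson bound at p = 0, n = 1000 is 0.0038 under the standard
two-sided formula implemented here; published tables using a different
Wilson variant can show smaller values (e.g. 0.0024), and no attempt is
made to reproduce those.

# MDC population-tree inference

`extra_lineages()` scores one gene tree against a candidate population
tree: two gene lineages may coalesce inside a population branch only when
the leaf set of their gene-tree ancestor is drawn entirely from populations
below that branch, so the lineage count at the top of the branch above node
`v` equals the number of maximal gene-tree clades whose alleles all come
from `v`'s populations; the score sums the excess over one across branches.
Gene-tree polytomies are never auto-resolved: they count as simultaneous
divergences, so lineages separated by a polytomy remain separate below it.
Branch lengths are ignored (topology-only scoring) — how lengths could
re-weight the parsimony criterion is deliberately left out, as no defined
convention exists for it.

`mdc_search()` hill-climbs over rooted topologies with subtree-prune-regraft
moves from each gene tree's induced population topology plus random Yule
starts, storing up to 100 tied trees; `mdc_exhaustive()` enumerates all
rooted topologies (105 for five populations) as an independent check, and
the two agree on every tested 5-population instance.

# Population-genetic statistics

For a group of n sequences, `segregating_sites()` uses *complete deletion*
within the group (columns containing any gap or ambiguity in the group are
excluded, giving a stable effective length `L_eff`), and Watterson's
estimator is `theta_W = S / (a_{n-1} L_eff)` with
`a_{n-1} = sum_{i<n} 1/i`. Pairwise statistics (`pairwise_diversity()`,
`between_group_divergence()`) use *pairwise deletion* and uncorrected
p-distances. Ambiguity codes are treated as missing, like gaps. The split
convention (complete deletion for S, pairwise for π) is reported in the
output because the deposited-data software this mirrors does not print its
exact convention; on clean simulated data the choice is immaterial, and on
real data the reproduction tolerance (±0.002 per site) absorbs it.
Statistics are computed on the concatenated matrix by default, with
per-locus computation over a partition as an option. Which sequences count
as "incipient species" to exclude is entirely the caller's grouping
decision, never inferred.

A clock utility (`lengths_to_time()`) converts substitution branch lengths
to time with a default rate of 0.01909 substitutions/site/My, a
fossil-calibrated butterfly rate; ages are reported with the deepest leaf
at 0, increasing rootward. Closed age intervals are attached per node and
`temporal_consistency()` reports, per codivergence, whether the mimic and
model 95% age intervals intersect (touching endpoints count as overlap;
missing intervals report "unknown").

# What the generators emulate — and what they do not

`simulate_cophylogeny()` grows the model tree as a Yule process (exponential
waiting times, rescaled to a set height) and lets mimic lineages track it:
at each model speciation a resident mimic lineage codiverges with
probability `p_codiv`, else follows one daughter; along each branch it may
die, duplicate, or duplicate-with-switch, with switch targets drawn
uniformly among model branches alive at the event time, so simulated
histories are time-consistent. The defaults are pure codivergence
(`p_codiv = 1`, all else 0) — the degenerate setting in which the mimic is
provably isomorphic to the model and reconciles at cost 0, used as the
power condition. `simulate_gene_trees()` is a standard neutral multispecies
coalescent (pairwise rate 2/θ per branch); `simulate_alignment()` evolves
JC69 sequences from a uniform root. With a per-site rate of 1 the expected
single-population pairwise diversity equals θ, which the estimator-recovery
study verifies (mean Watterson estimate within 10% of the simulated θ at
n = 10, L = 5000; the small downward bias is finite-site saturation).

These generators deliberately omit migration/gene flow between populations,
selection, recombination within loci, and rate heterogeneity across sites
or lineages. Real *Heliconius* data have all four, plus alignment error and
unbalanced sampling; passing the recovery and calibration tests therefore
shows the estimators and tests are correct under their own assumptions, not
that those assumptions hold for any particular empirical matrix.

## Reproducibility

All stochastic components take a single seed; replicate substreams are
derived with a fixed linear-congruential step (`substream_seed()`), so any
replicate can be regenerated in isolation. Problem sizes used by the
bundled studies — 500 calibration simulations at 199 replicates, 200 power
simulations, 200 recovery replicates at L = 5000, 12 MDC instances, 1000
discordance draws — were chosen as the smallest sets for which the binomial
or Monte-Carlo noise is clearly below the effect being checked.

# Known limitations

* The reconciliation enumerates co-optimal solutions only up to the cap and
  does not search Pareto sets over unspecified cost regimes; sweeping a
  user-supplied grid of cost vectors is the supported approximation.
* Switch timing is unchecked inside the dynamic programme; on trees with
  age intervals, `temporal_consistency()` provides the post-hoc check for
  codivergences only.
* The MDC hill-climb can in principle stop at a local optimum on larger
  population sets; the exhaustive reference is limited to ≤ 8 populations.
* Monte-Carlo p-values from tied integer costs are conservative at small
  leaf counts, as quantified above.
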