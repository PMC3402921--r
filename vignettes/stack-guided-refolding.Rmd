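---
title: "Stack-guided search for low-barrier RNA refolding pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stack-guided search for low-barrier RNA refolding pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackpath)
```

## The problem

Conformational switches — riboswitches, attenuators, viral leaders — are
RNAs that adopt two alternative secondary structures `A` and `B`. How
easily the molecule converts between them is governed by the *energy
barrier* of the refolding pathway: the free-energy difference between the
highest-energy structure visited along the way (the saddle point) and the
start structure. Finding the minimum-barrier pathway is NP-hard even when
intermediates are restricted to pairs of `A ∪ B`, so practical tools are
heuristics.

Most heuristics walk from `A` towards `B` choosing the next neighbour
structure by free energy (greedily or semi-greedily). On a rugged
landscape such walks get trapped. This package takes a different route:
pathways are *whole objects* — action chains — and the search mutates
whole pathways, guided by the formation and destruction of helical
stacks, while selection (and only selection) looks at energy barriers.

## Representation: action chains

A pathway from `A` to `B` is written as an ordered sequence of actions
`add(i,j)` / `del(i,j)`, each toggling a single base pair; a sequence is
a valid chain when every action applies without *conflict* (a position
already paired, or a deleted pair absent) or *clash* (a crossing pair,
which would create a pseudoknot) and the final structure is `B`. Valid
chains and pathways are in one-to-one correspondence, reordering a chain
yields a new pathway with the same endpoints, and inserting a
complementary `add`/`del` pair yields an *indirect* pathway that visits
pairs outside `A ∪ B`. All three facts are exploited by the mutation
operators.

A `pathway` record carries the energy profile `E(S_0) … E(S_m)`, the
saddle index, the barrier `max_t E(S_t) − E(S_0)` and a tie-break
statistic. We take the saddle over *all* structures including both
endpoints, which guarantees `barrier ≥ max(0, E(B) − E(A))`; this is the
usual convention in the barrier literature (the alternative — interior
structures only — can report barriers below the endpoint energy
difference, which is not meaningful for kinetics).

## Fitness

Pathways are ordered by barrier; ties are broken by the mean energy
excess over `E(S_0)` across steps `1..m` (the start structure is
excluded, since its excess is identically zero), then by chain length
(shorter preferred). Residual ties are pinned by creation order so runs
are exactly reproducible. Energies are compared at 0.01 kcal/mol, the
print resolution of the evaluators, which stabilizes tie-breaking across
platforms.

## The evolutionary loop

The initial population holds the four *simple* pathways: delete all
pairs of `A − B` stack by stack, then add all pairs of `B − A` stack by
stack, with each stack degraded/formed either outermost-first or
innermost-first (2 × 2 combinations). Stack-wise order avoids the
entropic penalty of scattering lone pairs across open loops.

Each generation, every parent produces offspring through five mutation
strategies:

* **M1** relocates one action within its feasible interval — the
  contiguous range of target positions that keep the chain valid,
  computed by outward scanning with full revalidation. The target is
  drawn with linearly decreasing weights towards the back for additions
  (they should happen early) and towards the front for deletions (late),
  `weight ∝ rank^β` with `β = 1` by default.
* **M2** swaps two uniformly chosen actions, redrawing on invalidity.
* **M3** inserts a complementary action pair: a new `add(i,j)` (drawn
  uniformly from pairs neither conflicting nor clashing with the anchor
  structure) with its deletion placed back-loaded — a freshly formed pair
  should not be removed immediately — or, symmetrically, a temporary
  deletion with a later re-addition.
* **M4** forces a whole stack, compatible with the anchor structure, to
  form immediately after the anchor, innermost pair first; additions
  already present later in the chain are relocated forward (M1
  mechanics), missing ones are inserted with complementary deletions (M3
  mechanics).
* **M5** anchors at a deletion and forces an *incompatible* stack to
  form, deleting each blocking pair just before the addition it blocks.
  Members are placed outermost-first: the outer pairs of the incoming
  stack nest around the remains of the outgoing one, so destruction and
  formation interleave rather than melting the molecule to a single
  strand first. (Innermost-first placement provably melts everything on
  instances like the built-in toy, because the innermost incoming pair
  crosses every remaining pair of the outgoing helix.)

The candidate pairs for M3 and the stack set `STA(x)` for M4/M5 are
precomputed per instance. `STA(x)` holds every *maximal* run of at least
`min_stack_len = 4` consecutive admissible pairs (canonical A·U, G·C and
wobble G·U, with a minimum hairpin loop of 3). Sub-stacks are not listed
separately: the operators work with the difference set `stack − S_t`, so
sub-stacks add no reachable moves while inflating the candidate set.

Selection keeps the best `l2 = 5` offspring per parent plus the best
`l1 = 10` pathways of the previous population (elitism) in the offspring
list; the next population is the best `l3 = 100` of that list, after
dropping duplicate chains to protect diversity. Per-strategy offspring
budgets adapt: strategy `y` receives `max(L_min, (b_y/l_y) / Σ(b/l) × L)`
offspring, where `b_y` counts its offspring that made the population —
strategies that worked get more draws, the rest are floored at
`L_min = 3`. The first generation splits `L = 100` uniformly.

The search stops when the barrier reaches the floor
`max(0, E(B) − E(A))` (within 1e-6; the literal `|E(B) − E(A)|` of some
formulations is available behind `literal_floor = TRUE`, but it is not a
true lower bound when `E(B) < E(A)`), when no improvement occurred over
`gamma = 5` consecutive generations, or when `MAX = 10` generations have
passed and the last one brought no improvement. "Improvement" here means
a lower (rounded) barrier. We deliberately do not use the full tie-broken
fitness in the stopping rules: M3 insertions can lower the mean-excess
tie-break indefinitely by absorbing stabilizing detours (on the built-in
toy, chains grew from 8 to 62 actions over 30 generations without the
barrier moving), so a fitness-equality plateau would never trigger.

## Energy models

Two backends implement the same contract (pure function of sequence and
structure; the open structure has energy 0):

* **turner** shells out to ViennaRNA's `RNAeval` with `-d1` dangling
  ends. The default parameter set is Turner-1999, the set in common use
  when the pathway-barrier literature standardized on `RNAeval -d1`
  evaluation; `turner2004` (ViennaRNA's default) is selectable. All
  structures of a generation are evaluated in a single subprocess call
  and memoized, which is behaviourally invisible.
* **simple** is a self-contained nearest-neighbour model: a 6 × 6
  stacking table (canonical + wobble, symmetrized under strand reversal,
  all entries negative), logarithmic hairpin/bulge/internal-loop
  penalties of the form `a + b·log(size)`, and an affine multiloop term.
  It exists so that the whole machinery — search, oracle, tests — runs
  with zero external dependencies, and it makes no claim to match Turner
  values. Because every stacking term is negative and loop penalties grow
  with loop size, extending a helix inward never raises the energy.

## The exact direct-pathway oracle

For instances whose pair union `A ∪ B` has at most 16 pairs, the package
solves the restricted (direct-pathway) problem exactly: states are the
valid subsets of the union, edges single add/del moves, and the optimal
bottleneck (minimax energy) path is found by sweeping states in order of
increasing energy with a union-find until the endpoints connect. The
certificate chain is recovered by breadth-first search inside the
threshold subgraph, with ties broken by fewer steps and then lexicographic
state order, so the certificate is deterministic. The oracle bounds the
evolutionary search from above on small instances: indirect detours can
only match or beat the direct optimum, and the test suite checks this
dominance on synthetic instances.

## Synthetic instances

`random_instance()` plants helices (a random 4–5-nt strand, a 3-nt loop,
its reverse complement) along a random sequence, enumerates the stack
set, and draws each endpoint structure as a union of mutually compatible
stacks. This emulates what the search must cope with on real switches —
alternative helices competing for the same strand segments, including
crossing (mutually exclusive) helices — while staying small enough to
verify against the exact oracle. It does not emulate everything about
real switches: natural sequences have longer helices interrupted by
bulges, non-canonical pairs, and barriers an order of magnitude larger.
Passing tests on synthetic instances therefore demonstrate correctness
of the machinery and sane search behaviour, not benchmark performance on
natural riboswitches.

## Problem sizes and reproducibility

The test suite and the acceptance script run the built-in 16-nt toy
switch with the reference parameter configuration (`MAX = 10`,
`gamma = 5`, `L = 100`, `l1 = 10`, `l2 = 5`, `l3 = 100`, `L_min = 3`)
for the deterministic energy checks, and a reduced search budget
(`L = 25`, `l1 = 5`, `l2 = 3`, `l3 = 20`, `MAX = 6`, `gamma = 3`,
`L_min = 1`) with the simple energy model for the stochastic property
checks (monotonicity over 20 seeded runs; best-of-5 dominance over the
exact direct optimum on 25 synthetic instances of 16–20 nt with pair
unions of at most 10). These sizes keep a full run of everything on a
single core comfortable while leaving the checked properties — which are
contracts of the algorithm, not artifacts of a budget — fully exercised.
Every stochastic component draws from R's RNG under an explicit seed:
identical seed and configuration reproduce the trace, the winning chain
and the reports byte for byte.

## Worked example

```{r toy, eval = FALSE}
fit <- stackpath(
  "GGGGAAAACCCCUUUU",
  "((((....))))....",     # A: the GC helix,  E = -6.60 kcal/mol
  "....((((....))))",     # B: the AU helix,  E =  2.80 kcal/mol
  control = ea_control(seed = 1, energy = "turner")
)
summary(fit)
plot(fit, "profile")
```

The four simple pathways melt `A` completely before building `B`; the
best two reach a saddle of 5.50 kcal/mol, a barrier of
12.10 kcal/mol. The search improves on this with indirect pathways that
bridge the transition through the wobble helix
`(1,16),(2,15),(3,14),(4,13)` — on this toy it finds the direct-optimal
11.80 kcal/mol barrier within a few generations.

## Known limitations

* Pseudoknots, non-canonical pairs, multi-strand complexes and modified
  nucleotides are out of scope; structures are strictly non-crossing.
* The Turner backend requires the `RNAeval` executable on the `PATH`;
  without it only the simplified model is available.
* Chain revalidation is quadratic in chain length; the pure-R
  implementation targets switch-sized instances (tens to a few hundred
  nucleotides), not genome-scale screens.
* The discrete bias distribution for M1/M3 position choices is a linear
  ranking by default (`β = 1`); the original description of this class
  of operators leaves the exact shape open, so `β` is exposed as a
  configuration knob.
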