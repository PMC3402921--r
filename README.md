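# stackpath

Low energy-barrier refolding pathways between two secondary structures of
an RNA molecule, found by an evolutionary search whose mutation operators
are guided by the formation and destruction of helical stacks.

## The problem

Conformational switches (riboswitches, attenuators, viral leaders) flip
between two secondary structures `A` and `B` of the same sequence. The
kinetic feasibility of the switch is governed by the **energy barrier** of
the refolding pathway

    barrier(p) = max_t E(S_t) - E(S_0),

the free-energy gap between the highest-energy intermediate (the *saddle
point*) and the start structure, taken along a pathway
`A = S_0, S_1, ..., S_m = B` in which consecutive structures differ by one
base pair. Finding the minimum-barrier pathway is NP-hard, and greedy
energy-guided walks get trapped in the rugged RNA landscape.

`stackpath` represents a pathway as an **action chain** — an ordered
sequence of `add(i,j)` / `del(i,j)` moves applied to `A` with no conflicts
(double-paired bases) or clashes (pseudoknots) — and evolves a population
of whole chains. Five mutation operators reorder actions (M1, M2), insert
complementary add/del detours that visit pairs outside `A ∪ B` (M3), force
the formation of a compatible helix stack (M4), or convert between
incompatible stacks by interleaving deletions and additions (M5).
Selection is by barrier, with mean energy excess and chain length as
tie-breaks; elitism, per-parent offspring caps, and adaptive per-strategy
offspring budgets maintain diverse, improving populations.

Energies come from ViennaRNA's `RNAeval` (Turner nearest-neighbour model,
`d1` dangling ends, Turner-1999 parameters by default) or from a built-in
dependency-free simplified nearest-neighbour model. An exact minimax
(bottleneck) solver for the restricted problem over *direct* pathways is
included as an independent oracle for small instances, along with a
synthetic instance generator.

## Worked example

The built-in toy switch is a 16-nt sequence whose start structure is a
four-pair GC helix and whose end structure is the crossing four-pair AU
helix:

```r
library(stackpath)
fit <- stackpath("GGGGAAAACCCCUUUU",
                 "((((....))))....",
                 "....((((....))))",
                 control = ea_control(seed = 1, L = 25, l1 = 5, l2 = 3,
                                      l3 = 20, MAX = 6, gamma = 3,
                                      L_min = 1, energy = "turner"))
fit
```

```
Stack-guided refolding pathway search
Sequence (16 nt): GGGGAAAACCCCUUUU
A:  ((((....))))....   E = -6.60 kcal/mol
B:  ....((((....))))   E = 2.80 kcal/mol
Best pathway: 16 actions, barrier 11.80 kcal/mol (saddle 5.20 at step 13)
Energy model: turner (turner1999, d1)
```

`E(A) = -6.60 kcal/mol` is the Turner free energy of the GC helix. The
best of the four *simple* pathways (melt `A` completely, then build `B`)
has saddle 5.50 and barrier `5.50 - (-6.60) = 12.10 kcal/mol`; the search
improves on it, reaching the barrier 11.80 kcal/mol that the exact
direct-pathway oracle confirms as optimal among direct pathways:

```r
m <- load_energy_backend("turner")
exact_direct_barrier(m, rna_seq("GGGGAAAACCCCUUUU"),
                     parse_db("((((....))))...."),
                     parse_db("....((((....))))"))$barrier
#> [1] 11.8
```

`summary(fit)` prints the full pathway table (step, action, dot-bracket,
energy), `plot(fit, "profile")` the energy profile, and
`plot(fit, "trace")` the barrier by generation. Equal-barrier chains may
retain neutral add/del cycles below the saddle; they do not affect the
barrier and disappear when a cleaner chain of the same barrier is found.

A command-line interface is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("..", "exec", "stackpath", package = "stackpath"))')" \
    run --instance my_switch.txt --energy turner --seed 1 --out out/
```

where the instance file holds three lines: sequence, structure `A`,
structure `B`. `stackpath oracle --instance ...` prints the exact direct
optimum instead. Reports are a plain-text pathway table, a JSON run
report, and a CSV trace of the search.

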