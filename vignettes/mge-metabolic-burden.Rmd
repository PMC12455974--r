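---
title: "Quantifying the metabolic burden of mobile genetic elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the metabolic burden of mobile genetic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgeflux)
```

## The problem

Mobile genetic elements (MGEs) — conjugative plasmids, filamentous phage
— replicate inside bacterial hosts using the host's monomer pools and
energy. Even without lysis, producing plasmid DNA, phage ssDNA and
coat/pilus proteins diverts deoxynucleotides, amino acids and ATP away
from host biomass. `mgeflux` quantifies that conflict inside a
genome-scale metabolic model: the element is represented as a *biomass
pseudoreaction* (a fixed stoichiometric drain per gram of element
produced), attached to the host network, and the host-versus-element
tension is measured with the standard trio of constraint-based analyses
plus a batch dynamic simulation of cross-feeding communities.

## The flux analyses

All analyses operate on the LP

$$\max Z = c^\top v \quad \text{s.t.} \quad S v = 0,\; lb_i \le v_i \le ub_i$$

where $S$ is the stoichiometric matrix, $v$ the flux vector
(mmol gDW$^{-1}$ hr$^{-1}$) and $c$ the objective. `fba()` solves this
LP; `pfba()` additionally minimizes $\sum_i |v_i|$ while holding
$c^\top v$ at (a fraction of) the optimum; `fva()` reports the min/max of
each $v_i$ over the same near-optimal set.

Because no linear-programming package is available in this R stack, the
package carries its own exact solver, `solve_lp()`: a dense two-phase
primal simplex with Bland's anti-cycling rule, bounded variables handled
by shifting/negation/splitting plus explicit upper-bound slack rows.
Bland's rule guarantees termination; the price is speed, which is
irrelevant at the package's intended desk scale (tens of reactions) but
makes genome-scale FVA (thousands of reactions × 2 LPs each) a
patience-requiring batch job. Numerical conventions:

* solver pivot/feasibility tolerance `1e-9`; assertions on solutions
  (steady state, bound and containment checks) use the looser `1e-6`;
* the objective sense is always maximize — minimization is expressed by
  negating $c$;
* `pfba()` linearizes $\sum|v_i|$ by splitting each flux into
  nonnegative forward/reverse parts, so the problem stays an exact LP
  (no quadratic solver). Under degenerate optima the particular
  minimal-total-flux vertex is solver-dependent; downstream metrics are
  designed not to depend on the choice beyond the stated tolerances;
* `fva()` defaults to `fraction_of_optimum = 1` (the optimal face
  itself, which is well defined under degeneracy); the fraction is
  exposed because values slightly below 1 can be numerically gentler on
  highly degenerate models.

Every analysis is cross-checked in the test suite against
`enumerate_flux_vertices()`, a brute-force enumeration of basic feasible
points of the flux polytope that is exact for the ≤ 12-reaction fixture
networks. The FBA optimum must match the best vertex and the FVA range
must match the coordinate span of the optimal face's vertices.

## Building an element's biomass pseudoreaction

From the element's composition, per particle:

* nucleotide counts $N_i^{tot} = C_g (N_i^G + N_i^{int})$, where $C_g$
  is the genome copy number per particle (1 for both a conjugative
  plasmid and a filamentous phage), $N_i^G$ the genome count and
  $N_i^{int}$ the count in replication intermediates. dsDNA genomes
  contribute both strands; for ssDNA genomes the double-stranded
  replicative form can be added as the intermediate
  (`replicative_form = TRUE`, the default recommendation for
  filamentous phage; off by default so the choice is explicit);
* amino-acid counts $AA_j^{tot} = \sum_k C_k \, AA_j^k$ over proteins
  $k$ with per-particle copy numbers $C_k$;
* ATP demand: 4 ATP per amino acid polymerized, applied to the *total*
  amino-acid count (a peptide-bond count, `atp_per_bond = TRUE`, is
  available for sensitivity analysis); H$_2$O is consumed 1:1 with ATP
  and ADP, P$_i$ and H$^+$ are produced 1:1 (one hydrolysis event per
  ATP);
* PP$_i$: 1 per nucleotide incorporated, intermediates included.

Counts become stoichiometric coefficients in **mmol per gram of
element** by dividing by the particle's total molar mass (monomer counts
× monomer masses, genome + proteome) and multiplying by 1000. The
monomer masses are those of the *consumed free monomers* (dNTPs, free
amino acids) and the same masses are used in the total-mass
denominator, which makes the normalization identity

$$\sum_{\text{24 monomers}} \text{coeff} \times \text{molar mass} = 1000 \; \text{mmol/g}$$

hold exactly by construction: one unit of pseudoreaction flux drains
precisely one gram of element per gram dry weight per hour. The identity
is asserted to `1e-6` on 50 random compositions in the tests.

Metabolite identifiers default to BiGG-style ids (`datp_c`,
`ala__L_c`, `atp_c`, …) and are fully remappable through the
`monomer_table`; an id of `NA` omits that species, which is how the toy
hosts (which pool all amino acids into one species) are served. The
pseudoreaction is irreversible with bounds $[0, 1000]$, the usual
"practically unlimited" convention.

For conjugative pili, `pilin_copy_number()` converts pilus geometry into
propilin (traA) copies: a 5-start helix with 12.8 subunits per helical
turn and a typical maximum length of 20 µm. The axial pitch per turn is
*not* a universal constant and is a required argument; an explicit
copy-number table always overrides the calculator. The default costing
assumes a single pilus structure per particle.

## Carriage states

A carriage state fixes the objective and the forced element production:

| state | objective | plasmid lb | phage lb |
|---|---|---|---|
| WT (host-optimized) | host biomass | 0 | 0 |
| F128+ intermediate | host biomass | 0.9 | 0 |
| F128+ M13+ intermediate | host biomass | 0.9 | 0.06 |
| plasmid-optimized | plasmid | — | 0 |
| phage-optimized | phage | 0.9 | — |

Bounds are mmol gDW$^{-1}$ hr$^{-1}$. Because adding a lower bound only
shrinks the feasible set, the biomass optimum is provably non-increasing
from WT to single to double carriage — asserted across 20 seeded toy
hosts in the tests.

Two host edits mirror the engineered cross-feeding system: a *metB*
knockout (methionine auxotroph; `make_metB_knockout()`) and a
methionine secretor (`make_methionine_secretor()`) that couples 0.5 mmol
of extracellular methionine to each gram of biomass growth. The
coupling is written directly into the biomass reaction's stoichiometry
(the alternative — a separate coupled pseudo-exchange — is equivalent at
the LP level but adds a reaction; the direct edit keeps the export/growth
ratio exact in *every* optimal solution), and methionine transport is
made unidirectional so the secreted methionine cannot be reused.

## Conflict metrics

**FVA range overlap.** A reaction is *high conflict* between a
host-optimized and an element-optimized state when its two FVA ranges
share no value — closed intervals, so ranges meeting at a single
endpoint do not conflict. `find_conflicts()` reports the conflict set,
its fraction of all reactions, and per-subsystem fractions.

**pFBA demand fold-changes.** Per cellular subprocess $i$,

$$\log_2\!\left(\frac{\sum_i |F_i^P| / \sum_k |F_k^P|}{\sum_i |F_i^H| / \sum_k |F_k^H|}\right)$$

with $F^P$ the parsimonious fluxes under the element objective and
$F^H$ under the host objective. Absolute values capture demand
magnitude; reactions whose flux *direction* flips between the states
(both magnitudes above `zero_tol = 1e-9`) are dropped from numerators
and denominators and listed. The denominator runs over *all* reactions
of the model, exchanges and pseudoreactions included (the
`exclude_exchanges` flag restricts it); fluxes at or below `zero_tol`
contribute zero and never count as direction changes. A subsystem with
zero flux in exactly one state has no finite fold change and is flagged
`defined = FALSE` rather than erroring; a subsystem at zero in both
states reports 0.

## Batch dynamic FBA

`run_dfba()` simulates one to three species sharing a well-mixed batch
pool, in the style of COMETS-like platforms:

* per cycle, each species' exchange uptake bound is capped at
  $\min(v_{max},\; \text{amount}/(X \Delta t))$ with
  $v_{max} = 10$ mmol gDW$^{-1}$ hr$^{-1}$ by default — the coarse-grain
  linear cap that standard batch dFBA uses when no Michaelis–Menten
  parameters are given;
* every species is solved against the start-of-cycle pool (no update
  ordering bias), then biomass follows forward Euler,
  $X \leftarrow X (1 + \mu \Delta t)$, and the pool is updated from the
  exchange fluxes scaled by pre-update biomass;
* if several species would jointly overdraw a metabolite, all of its
  consumers' caps are tightened by the common factor that zeroes the
  pool and the cycle is re-solved — mass-conserving and
  order-independent;
* an infeasible species LP in a cycle means $\mu = 0$ and no exchange
  for that species that cycle, not an exception;
* "excess" nutrients are finite 1000 mmol pool entries rather than
  infinite bounds, so depletion stays representable;
* no death term; maintenance enters only through a model's own ATP
  maintenance reaction if it has one.

Default schedule: 200 cycles of 1 hour, inocula of $10^{-8}$ gDW per
species ($\approx 3.33 \times 10^4$ cells at the 3e-13 g E. coli dry
weight used by `cells_from_biomass()`), carbon at 2.78e-4 mmol. The
simulation is fully deterministic — two runs of one configuration are
bit-identical.

`biomass_normalized_secretion()` converts a trajectory into the
mmol gDW$^{-1}$ accumulation series used to compare excretion profiles
across carriage states.

## What the synthetic fixtures emulate — and what they do not

`make_toy_host()` generates ~13-reaction hosts with the subsystems the
conflict metrics need (transport, energy metabolism with a
respiration/fermentation branch, methionine/amino-acid/nucleotide/lipid
biosynthesis, biomass). The respiration capacity is deliberately scarce
relative to energy demand (cap drawn from U[0.6, 1.2] mmol gDW$^{-1}$
hr$^{-1}$ against carbon uptake of 10), so overflow byproduct export is
part of the optimal operating regime, as in fast-growing E. coli — this
is what lets a forced element drain visibly raise per-biomass byproduct
excretion. Yields and biomass coefficients vary with the seed inside
ranges where generation verifies a positive growth optimum.

`make_conflict_fixture()` is the analytic branch-point network: one
limited precursor feeds either a host-biosynthesis branch or an
element-precursor branch, so at either optimum the whole supply runs
through one branch and the other is pinned at zero. Its certified
conflict set (the four branch/sink reactions) is re-derived by the
vertex oracle inside the test suite, never merely stored.

`make_mutualism_fixture()` encodes the obligate cross-feeding pair: a
methionine auxotroph that obligately excretes an overflow byproduct
(4 mmol per gDW; its only energy route is fermentation) and a secretor
that can only grow on that byproduct and exports 0.5 mmol methionine
per gDW. The media carry 2.78e-4 mmol carbon, a 1000 mmol mineral pool,
and a 5e-13 mmol methionine trace. The trace is the fixture's ignition:
growth-coupled secretion on both sides means a strictly zero pool is a
fixed point, and 5e-13 mmol is small enough that the auxotroph alone
gains < 1% biomass, yet the cross-feeding loop gain (≈ 50 per relay)
amplifies it to carbon exhaustion within tens of cycles. The methionine
requirement (0.01 mmol/gDW) is of the order of real proteomes; the
element burden variant attaches the canonical toy element's
pseudoreaction mapped onto the auxotroph's carbon/energy pools.

These fixtures are deliberately small (exact vertex enumeration, exact
carbon audits via assigned formula units). Passing tests therefore
demonstrate the *mechanics* — LP correctness, normalization identities,
conflict logic, mass-conserving dynamics, qualitative burden directions
— not quantitative agreement with any real organism: toy yields are
round numbers, there is no maintenance energy, no proteome constraint,
and single pooled amino-acid/nucleotide species replace 24 real
monomers.

## Problem sizes and reproduction

The shipped tests and the acceptance script run entirely at desk scale:
≤ 13-reaction hosts, ≤ 6-reaction oracle fixtures, 50-spec normalization
sweeps, 20-seed monotonicity sweeps, and dFBA runs of 60–200 cycles —
seconds to a couple of minutes in total. The genome-scale reproduction
(`reproduce_genome_scale_conflicts()`) consumes a real host model
(BiGG iJO1366), GenBank-derived element compositions and a per-protein
copy-number table; those inputs are multi-megabyte public downloads the
package does not bundle, and exact conflict counts additionally depend
on the exact copy-number table used. See the function's help page for
the expected input layout.

## Known limitations

* The simplex solver is dense and Bland-pivoted: robust and exact on
  small problems, slow on genome-scale ones.
* No loopless FBA, thermodynamic constraints, or proteome-allocation
  variants; no MOMA; no gene-expression integration.
* SBML input is delegated to an external COBRApy conversion when
  available; the native dialect is the community JSON schema.
* dFBA has no spatial structure, lag phases, death, stochasticity, or
  plasmid-loss dynamics; uptake kinetics are the linear cap above.
* Pseudoreactions cover nucleotide, protein and polymerization-energy
  costs only — no lipid or carbohydrate element components, and no
  extracellular transport of phage particles.
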