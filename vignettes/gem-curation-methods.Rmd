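---
title: "Models and methods behind gemcurator"
author: "gemcurator authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gemcurator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemcurator)
```

# Scope

gemcurator packages the computational stages of building and
validating a genome-scale metabolic model (GEM) of a metabolically
versatile bacterium: evaluating homology-transferred draft
gene–protein–reaction (GPR) rules over BLAST cutoff grids, structural
quality control, minimal-addition gap filling, biomass objective
construction, phenotype-microarray validation, and dynamic flux
balance analysis against kinetic growth data. The organism-scale
inputs of a real reconstruction — a genome, template models, BLASTp
runs, curated literature — are external artifacts; the package instead
ships seeded generators that emulate each input with known ground
truth, so every stage is exercised end to end without downloads. What
a passing test suite shows is therefore that the *procedures* are
correct on networks whose answers are known by construction; it does
not certify any particular organism's reconstruction.

# The constraint-based model

A model is a set of compartmentalised metabolites and reactions with
signed stoichiometry, flux bounds in mmol·gDW⁻¹·h⁻¹, and boolean GPR
rules (`and` = protein complex, `or` = isozymes; the empty rule marks
an orphan reaction). Flux balance analysis solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub$$

with the biomass pseudo-reaction as the default objective, so the
optimum is the specific growth rate in h⁻¹. Exchange reactions are
written `met_e ↔ ∅`; uptake is a negative exchange flux, and a medium
specification maps exchange ids to maximal uptake magnitudes (an entry
of 10 sets the lower bound to −10; absent entries close uptake).
Non-finite bounds are clamped to the global ±1000 convention, which
keeps every LP bounded.

## The LP core

No dedicated linear-programming package is part of the package's
dependency footprint; the solver is a dense two-phase tableau simplex
(`R/lp.R`) with Dantzig pricing, a Bland anti-cycling fallback, and a
1e-9 feasibility tolerance. This is a deliberate design choice: the
networks this package targets in its tests and analyses are small
(tens of reactions), a dense tableau is simple to audit, and the test
suite validates the solver against brute-force vertex enumeration of
the flux polytope on every fixture with at most six reactions, plus
randomized box-bounded LPs. Degenerate alternate optima are real in
FBA; only the objective value is contract-stable, and flux vectors are
reported but never asserted.

Qualitative growth calls use a threshold of 1e-6 h⁻¹ on the optimal
biomass flux; reported fluxes below 1e-9 are clamped to zero. Gene
essentiality defaults to a knockout/wildtype ratio below 0.05, a
conventional fraction, and is configurable.

## Energy-leak detection

Erroneous free-energy generating cycles are a classic reconstruction
artifact. The check closes the uptake of every exchange (whatever
medium the model carried — the check is invariant to it), adds in turn
a dissipation reaction for ATP (`atp + h2o → adp + pi + h`), NADH and
NADPH, and maximises its flux. Any positive maximum can only be fed by
a thermodynamically infeasible internal loop; the support of the flux
vector names the participating reactions. Currency metabolites missing
from a model skip that check with a warning rather than failing,
because a toy network without an energy subsystem is not thereby
wrong.

# Structural quality control

Balance checking parses Hill-notation formulas and sums
coefficient-weighted element counts and charges per reaction; charge
is computed independently of the hydrogen count and both are reported.
Exchange, sink, demand and biomass pseudo-reactions are exempt (the
biomass reaction is not elementally balanced by design), and a
reaction touching any formula-less metabolite is reported `unknown`
rather than failed. Dead-end classification treats a reaction with
`lb < 0 < ub` as producing and consuming everything it touches — a
repo convention, since reversibility conventions differ between
toolboxes — and labels disconnected metabolites by motive:
`single_reaction`, `substrate_only`, `product_only`.

# Gap filling as a MILP

Gap filling opens a binary indicator $y_i$ per universal candidate
reaction, couples fluxes by $lb_i y_i \le v_i \le ub_i y_i$ (big-M =
1000, the global bound), requires the target flux to reach ε, and
minimises $\sum_i w_i y_i$ with unit default weights. ε defaults to
1e-3 mmol·gDW⁻¹·h⁻¹ — small enough to count as producibility, large
enough to sit far above LP tolerances. The branch-and-bound explores
the LP relaxation depth first; the integrality tolerance (1e-8) is
deliberately far below ε/1000, because the relaxation can satisfy the
target by opening a candidate at $y = \varepsilon/1000$ and such a
value must branch rather than round to zero. Ties among equal-cost
solutions resolve to the fewest additions first (which rules out
zero-weight free riders) and then to the lexicographically smallest
reaction-id set, so results are reproducible. The returned set is
re-validated by a plain FBA on the augmented model before being
reported — a post-condition enforced in code, not just in tests. The
iterative mode processes growth conditions in order, carrying accepted
additions forward and recording per-condition provenance by re-testing
each earlier addition's necessity.

# Draft evaluation over cutoff grids

Homology transfer retains a hit when `e_value ≤ max_e`,
`alignment_length ≥ min_len` and `identity ≥ min_id`, all inclusive at
the boundary. "Query length" is interpreted as alignment length in
amino acids; a query-coverage criterion is selectable instead, which
is what manual curation stages typically use (e.g. e ≤ 1e-10,
coverage ≥ 80%). Scoring against a curated reference counts gene
*slots* per reaction (a wrong gene recurring in four reactions is four
accumulative false positives) and separately the distinct genes behind
them. The default grid is 8 e-values × 6 lengths × 8 identities = 384
combinations spanning e ∈ [1e-30, 1e-5], length ∈ [50, 150] aa,
identity ∈ [20, 40]%; the factorization of the 384 points inside those
spans is a package choice, fully configurable, since only the spans
and the total are given externally. Two properties are enforced as
invariants: reference gene-slot conservation (TP + FN is constant
across the grid) and cutoff monotonicity (relaxing any single cutoff
weakly increases both TP and FP and weakly decreases FN).

# Biomass objective construction

Amino-acid coefficients come from residue mole fractions $f_i$ of the
proteome scaled into mmol·gDW⁻¹ by
$1000 \cdot \text{mass fraction} \cdot f_i / \sum_j f_j M_j$, where
$M_j$ are residue masses (monomer minus water, so polymerization water
is handled implicitly). DNA base fractions are counted over both
strands (forcing A=T, G=C); RNA uses the sense strand with T read as
U, a documented approximation of the average transcript pool.
Constituents are grouped into nine clusters — amino acids, cell wall,
pigments, cofactors, RNA, DNA, carbohydrates, minerals, miscellaneous
— and the assembled reaction must consume exactly 1 g per gDW within
1e-3. Growth-associated maintenance defaults to GAM = 40 mmol
ATP·gDW⁻¹ and the non-growth analogue to NGAM = 3 mmol·gDW⁻¹·h⁻¹:
typical Gram-negative values, configurable, and stated prominently as
assumptions because measured values are condition- and
organism-specific. Pigment and remaining-cluster coefficients are
user-supplied configuration, not code.

# Phenotype validation

Experimental growth on a substrate is a strict OD600 increase above
0.02 within a 96-h horizon. Each mapped substrate is simulated on a
fresh copy of the base medium with every alternative source of the
tested nutrient class closed; unmapped substrates are excluded from
the confusion matrix rather than counted as false negatives, mirroring
how compounds without defined assimilation pathways are excluded from
plate validation. The statistic panel uses the standard formulas; any
0/0 ratio is defined as 0 and flagged. Reported values are rounded
half-up to two decimals (the presentation convention of published
panels) with raw values retained, and the growth-rate accuracy metric
is relative error, floored at zero, as an integer percent — this
reproduces three of five published aromatic-compound rows exactly and
the other two within one unit, so it is documented as the inferred
metric rather than a stated one.

# Dynamic FBA

The simulator is the static-optimization approach: per step, each
tracked substrate's uptake bound is
$\min(v_{\max}, S/(\bar{X}\,\Delta t))$, an FBA is solved, biomass
updates exponentially ($X \leftarrow X e^{\mu \Delta t}$, exact for
constant μ within the step) and concentrations update with the
step-average biomass $\bar{X} = X(e^{\mu\Delta t}-1)/(\mu\Delta t)$.
Because $\bar{X}$ depends on the step's own μ, a short fixed-point
iteration resolves the pair, and the same $\bar{X}$ multiplies both
the cap and the update so the pool cannot be overdrawn; a genuinely
negative concentration is an assertion failure, never clamped (only
sub-1e-6 numerical dust is snapped to zero). Default Δt is 0.1 h; the
closed-form single-substrate batch solution is reproduced to
first-order convergence, and when organic substrates are exhausted
with a CO₂ exchange open, growth continues at the autotrophic FBA
value — the regime switch emerges from the LP, with no special
casing. Regulation and inhibition are deliberately absent from the
kinetics.

Calibration matches the simulated endpoint biomass to the observed
final point within 0.5% by log-scale bisection of a common scale on
the uptake rates; co-substrate rates are apportioned proportionally to
each substrate's observed linear depletion slope before the common
scale is fitted. Fit statistics interpolate the trajectory linearly to
the observation times and report Pearson r² with the base-10 log of
the two-sided p-value from the t-transform; r² is sign-blind, which is
documented rather than "fixed".

# Synthetic data and what it does not emulate

Each generator derives an isolated RNG stream from (seed, label), so
outputs are bit-reproducible and adding a generator never perturbs
existing fixtures; the caller's RNG state is untouched. Ground truth
is always constructive — route-yield arithmetic for optima, set
construction for homology tables, graph reachability for plate calls,
the closed-form batch solution for kinetics — never the module under
test, so validation is non-circular. Study conditions are fixed at
generation defaults: planted homology cutoffs at e = 1e-5, 100 aa,
30% identity (the final draft-selection values), a 10% plate
call-error rate with 500 wells, 1%-noise exponential-phase kinetic
series with the stationary phase trimmed.

The generators do not emulate realistic genome-scale topology
(thousands of reactions, cofactor coupling, alternative optima at
scale), sequence evolution, or plate artifacts beyond independent call
flips. Passing tests show the machinery is correct where answers are
provable; organism-scale accuracy claims require the real inputs and
are out of scope.

# Problem sizes and numerical choices

The shipped analyses and tests run on networks of 4–40 reactions, a
384-point cutoff grid over ~75 hits, 500-well plates, and dynamic
simulations of 10³ steps — sizes chosen so the exhaustive oracles
(vertex enumeration, subset search, bipartite scans) stay tractable
while still exercising every code path. Key tolerances: LP feasibility
1e-9, flux zero-clamp 1e-9, producibility and leak thresholds 1e-6,
MILP integrality 1e-8, biomass mass check 1e-3, calibration endpoint
0.5%. Stoichiometric coefficients are stored as doubles and compared
with absolute tolerance 1e-9 (biomass coefficients are small).

# Known limitations

No flux variability analysis, parsimonious FBA, or thermodynamic
loop-law constraints (the leak check stands in for loop QC); no
Michaelis–Menten or inhibition kinetics; no annotation enrichment or
database queries; the dense simplex is not meant for
organism-scale LPs with thousands of reactions — swapping in an
industrial solver behind `solve_lp()` is the intended extension point.
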