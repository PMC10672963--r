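---
title: "Condition-specific flux-weighted pathways: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific flux-weighted pathways: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpath)
```

## The problem and the model

Classical pathway analysis maps expression changes onto manually curated
gene sets. Those sets ignore two things a metabolic network knows: that the
*role* of an enzyme depends on the condition (the same reactions consume a
metabolite under one medium and produce it under another), and that
reactions contribute *unequally* to a function, in proportion to the flux
they carry. fluxpath instead defines a pathway around a metabolic
*function* — the production or the consumption of one metabolite under one
growth condition — and weighs every reaction in it by its flux
contribution to that function.

The pipeline has four stages.

**1. Flux estimation.** The condition-specific flux state solves

$$\max_v \; c^\top v \;-\; F\,\lVert v\rVert^2
\quad\text{s.t.}\quad S v = 0,\; v_{lb} \le v \le v_{ub},$$

where $S$ is the stoichiometric matrix, $c$ selects the objective reaction
(biomass, or ATP production for the database presets), and $F$ (default
$10^{-6}$) is a small quadratic flux-length penalty. The penalty encodes
parsimony — a cell meets its objective with as little enzyme expenditure
as possible — and makes the optimum unique on the bounded feasible set, so
degenerate alternate optima (e.g. two equivalent parallel branches) are
resolved reproducibly: equal branches split the flux evenly, wasteful
branches are left at zero. A growth constraint can be fixed (e.g.
0.4 h⁻¹ aerobically, 0.26 anaerobically), a minimum, or "maximum of the
model's capacity", in which case biomass is maximized first and then
imposed as a lower bound before the stated objective is solved.

**2. Subnetwork extraction.** For a metabolite and a direction, a
breadth-first traversal of the *flux-oriented* network (reaction direction
= sign of its flux; inactive reactions removed) collects reactions within
$D$ reaction steps: backwards over producers for a production pathway,
forwards over consumers for consumption. Currency metabolites (ATP, NADH,
H₂O, ...; see `default_cofactors()`) are removed before traversal because
their shared pools connect everything to everything; a cofactor target is
itself exempt. The default $D = 3$ reflects that intermediate depths give
pathways long enough to integrate signal but local enough to remain
co-regulated; $D = 1$ is noticeably too short, and the results change
little between 2 and 5.

**3. Elementary-mode decomposition.** The extracted subnetwork is closed
by adding synthetic boundary reactions carrying exactly each unbalanced
metabolite's net imbalance, so the subnetwork flux is again a steady
state. That flux is then decomposed as $v_{sub} = \sum_k \lambda_k e_k$
with $\lambda_k \ge 0$ and each $e_k$ a support-minimal steady-state mode
(after direction-splitting so all fluxes are non-negative). Modes in which
the target metabolite is actually produced (or consumed) by a model
reaction are kept, summed with their weights, boundary reactions dropped,
and the result normalized to sum one: the **pathway weights**. Full
elementary-mode enumeration is intractable at genome scale, but on a
distance-bounded active subnetwork it is fast — that locality is what
makes the approach tractable.

**4. Perturbation scoring.** Given fold changes $f_i$ on a ratio scale
(1 = unchanged; `load_expression(log2 = TRUE)` exponentiates log-scale
input), a reaction score is the arithmetic mean over the genes catalyzing
the reaction, and the pathway perturbation score is the weight-normalized
sum $\sum_i w_i \cdot \mathrm{reaction\_score}_i$. Scores above/below 1
mean coordinated up-/down-regulation of the capacity for that function.
Significance comes from a permutation test: fold-change assignments are
permuted across the model's genes, both scores recomputed each round, and
the two-sided empirical p-value computed on the log scale,
$p = (1 + \#\{|\log s_{null}| \ge |\log s_{obs}|\})/(n_{perm}+1)$.

## Worked small example

```{r}
toy <- make_toy_model("diamond")
state <- solve_flux_state(apply_condition(toy$model, toy_condition(toy)))
tidy(state)
extract_pathway(toy$model, state, "D_c", "production", D = 3)
```

The fixed uptake of 1 splits evenly over the two equivalent branches
(0.5/0.5, the unique penalty-minimal solution), and the production pathway
for the end product weighs the uptake reaction twice as heavily as each
branch reaction — weights are flux contributions, normalized.

## Design choices where the design was open

* **Sign of the quadratic term.** A maximization with a positive-definite
  quadratic term would be unbounded; the only coherent reading of a
  "secondary flux-length objective" is $-F\lVert v\rVert^2$, i.e. length
  *minimization*, which is what the package implements.
* **QP solver.** The flux QP is solved by a dense primal-dual
  interior-point method written for this package (Mehrotra
  predictor-corrector, Schur-complement Newton steps, and a KKT-verified
  active-set polish so bound-active fluxes are exactly zero). An
  interior-point method is insensitive to the awkward scaling of this
  problem class — a near-linear objective with $10^{-6}$ curvature over
  stoichiometric coefficients spanning 0.1–60 — and repeated solves are
  bit-identical. Solver tolerances: duality gap $10^{-10}$, steady-state
  residual $\le 10^{-6}$ enforced on every returned state (typically
  $10^{-12}$ after polish).
* **Mode extraction.** Support-minimal modes are found by null-space
  compression: start from the residual flux (itself a steady state), move
  along null-space directions zeroing at least one reaction per step while
  staying non-negative, and stop when the support-restricted null space is
  one-dimensional — at that point the candidate spans it and no steady
  state with a strictly smaller support exists. Each subtraction of the
  largest non-negativity-preserving multiple zeroes another reaction, so
  at most `|support|` modes are produced and their weighted sum
  reconstructs the subnetwork flux to $10^{-8}$ per reaction (asserted in
  the tests against exhaustive enumeration on ≤12-reaction fixtures).
  SVD-based null bases, a fixed direction choice and a fixed sign
  convention make the decomposition deterministic.
* **Gene–reaction rules.** AND/OR structure is flattened to the set of all
  genes in the rule, because the reaction score averages over "all genes
  involved in catalysis" without distinguishing complexes from isozymes.
* **Missing expression.** Reactions without any measured gene are dropped
  and the remaining pathway weights renormalized. Imputing a neutral 1.0
  instead would shrink true signals by an amount that depends on coverage.
* **Cofactor list.** The removal list is a package decision (the standard
  currency set: ATP/ADP/AMP, NAD(P)(H), FAD(H₂), CoA, H⁺, H₂O, Pi/PPi,
  CO₂, O₂, NH₄, ubiquinone), overridable via `flag_cofactors()` or a
  one-name-per-line file; succinate and other carrier substrates are
  deliberately not on it. Cofactor *species* are also excluded from the
  closed subnetwork, because keeping their rows would re-introduce the
  spurious couplings the removal is meant to prevent.
* **Permutation scheme.** Genes are permuted globally across the model
  (not within pathway-size strata). When expression covers every model
  gene the permuted score is a fixed linear map of the permuted values
  and is computed by matrix multiplication; with partial coverage the
  assignment of which genes carry data is itself permuted.
* **Database merging.** Per (metabolite, direction), pathways from
  different conditions with Matthews correlation strictly greater than
  0.9 over the reaction universe are grouped by single linkage (connected
  components make the result independent of input order); merged weights
  are the member mean, renormalized. The 64 built-in growth conditions are
  1 standard glucose minimal medium + 20 amino-acid supplements × {aerobic,
  anaerobic} + 8 carbon sources × {normoxia, hypoxia, anoxia with nitrate},
  with the glucose/normoxia cell identical to the standard condition and
  not duplicated. Hypoxia is operationalized as an O₂ lower bound of −2
  mmol/gDW/h (the reduced-oxygen value used for the anaerobic-shift
  condition); these bounds are preset values, documented here, not
  measurements.

## What the synthetic data do and do not show

The test fixtures are built for *provable* behavior: toy topologies
(chain, diamond, cycle, cofactor trap, wasteful branch) whose complete
elementary-mode sets are enumerable by brute force, and a ~60-reaction
synthetic reconstruction of E. coli central carbon metabolism
(`synthetic_ecoli_core()`, textbook stoichiometry with BiGG-style
identifiers — a stand-in written in code, not a published model file). On
these, the suite verifies exact conservation, oracle equivalence of the
decomposition, the scoring identities, permutation calibration under a
log-normal null (500 simulated datasets × 1000 permutations; problem sizes
chosen so the whole suite runs in well under a minute), and the canonical
TCA-cycle split of succinate handling under aerobic glucose growth:
production through CS → ACONTa/b → ICDHyr → AKGDH → SUCOAS, consumption
through SUCDi → FUM → MDH, with fumarate reductase absent aerobically.

What passing these tests does **not** show: that pathway scores are
well-calibrated on real transcriptomes (real fold changes are neither
independent nor log-normal), that the cofactor list is right for every
organism, or that results on a genome-scale reconstruction (thousands of
reactions, gapped annotations, isozyme-rich GPRs) match a curated
database. The synthetic central-carbon model has complete, clean gene
annotations and exactly consistent stoichiometry — real reconstructions
have neither.

## Degenerate inputs and numerical edges

Empty subnetworks (no active producer/consumer within $D$) yield an empty
pathway with a notice, not an error. Unscorable pathways (no gene with
data) propagate `NA` scores and are excluded from ranking. Fluxes below
`zero_tolerance` (default $10^{-9}$) are treated as inactive; decomposition
treats residual fluxes below $10^{-8}$ as exhausted but keeps its working
support floor at $10^{-12}$ so the residual stays an exact steady state.
Bounds at $\pm\infty$ are clamped to $\pm1000$ mmol/gDW/h, the
conventional default. Ties — equal expression values in rank
normalization, equal residuals in mode extraction — are broken
lexicographically so every code path is deterministic.

## Known limitations

The dense interior-point solver targets models up to a few hundred
reactions; genome-scale reconstructions need a sparse industrial solver
behind the same interface. The SBML reader covers the Level 3 + FBC v2
subset that BiGG exports (species/reaction prefixes, parameter-referenced
bounds, geneProductAssociation trees); exotic SBML features (initial
assignments, kinetic laws, groups-package subsystems) are ignored.
Database generation across the full 64 presets presumes the model defines
the preset exchange reactions; models lacking an exchange raise a
validation error listing the valid ids rather than silently skipping.
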