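---
title: "Constraint trees: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint trees: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtree)
```

# The modeling framework

A constraint-based metabolic model is a set of linear constraints over a
flux vector.  fluxtree represents every such system as a **constraint
tree**: an ordered, uniquely labeled hierarchy whose leaves are
`Constraint` objects — a sparse linear *value* over a global 1-based
variable space, bound to an *equality*, an *interval*, or nothing
(`AbsentBound`, for tracked quantities such as objectives).  The tree
imposes no semantics on its labels; the meaning of `fluxes/`,
`capacity/`, `members/` and so on is carried entirely by the builders that
create them, which is what makes the blocks freely recombinable.

Two combination operators cover all assembly needs:

* `mergeShared(a, b)` — recursive union of two trees over one variable
  space.  Leaf collisions are always an error; silent overwrites would make
  layered model building unauditable.
* `combineIndependent(a, b)` — shifts every variable index of `b` by
  `variableCount(a)` and then merges.  `a` is never modified, and `b`'s
  constraints are identical up to the shift, so independently constructed
  blocks (or copies of an entire member model) concatenate without any
  manual index arithmetic.

Solving goes through a single choke point: `flattenTree()` emits one row
per bounded leaf, ordered lexicographically by full path in byte order, so
the matrix a tree produces is a pure function of its contents — never of
construction history or locale.  `solutionTree()` maps an optimal variable
assignment back through the leaf values, returning results in the exact
shape of the model.

## Assumptions

* All values are linear; quadratic objectives are out of scope.
* Steady state: every metabolite balance row is an equality at zero.
* Exchange fluxes follow the COBRA sign convention (negative = uptake).
* Bound magnitudes at or above `1e30` are infinities; conventional ±1000
  COBRA bounds are kept finite deliberately.

# Reconstruction layers

`fluxBalanceConstraints()` emits the base FBA system (`fluxes/`,
`flux_stoichiometry/`, tracked `objective`).  `knockout()` re-binds the
flux of every reaction whose gene–protein–reaction (GPR) rule evaluates
false to `EqualTo(0)`; rules are parsed with `and` binding tighter than
`or`, and isozyme expansion (`gprToIsozymes()`) is a DNF with duplicate
and superset conjuncts removed, capped at 10,000 conjuncts (an error, not
a truncation).

`enzymeConstraints()` is a GECKO-style formulation: each isozyme and
direction gets a non-negative flux `w`, net fluxes couple as
`v = Σw_fwd − Σw_rev`, enzyme demands are tracked values
`g_p = Σ n_{p,i}(w_fwd/kcat_fwd + w_rev/kcat_rev)` (mmol gDW⁻¹), and each
capacity group bounds `Σ mw_p g_p` (g gDW⁻¹).  Group membership (e.g.
`membrane`, `cytosol`, `all`) is supplied by the kinetics table, never
inferred from the model.  Subunit stoichiometry multiplies enzyme demand;
counts default to 1 when rules come straight from GPRs.

`srbaConstraints()` adds the simplified resource-balance blocks at a fixed
growth rate μ, where they are all linear: protein synthesis fluxes with
growth dilution (`s_p = μ g_p`), ribosome utilization and capacity
(`Σ L_p s_p + L_R μ R ≤ k_t R`, including ribosome self-replication),
polymerization ATP costs added onto the matching metabolite balance rows,
a total proteome budget, and the growth objective re-bound to
`EqualTo(μ)` so the system becomes a feasibility problem.  Growth dilution
is applied to gene products and the ribosome only; metabolite and RNA
dilution are out of scope.  The exact published sRBA equation set lives in
supplementary material not available here, so the named blocks are
implemented in their simplest linear form, documented formula by formula
above, and all parameters are user-overridable.

Default `srbaParams()` values are literature-scale numbers for a
fast-growing bacterium, chosen once: translation rate 45000 aa h⁻¹
(12.5 aa s⁻¹), ribosome mass 2700 g mmol⁻¹ and length 7459 aa,
polymerization cost 4.3 mmol ATP per mmol amino acid, proteome budget
0.55 g gDW⁻¹.  The ATP hydrolysis mapping defaults to empty because
metabolite identifiers are model-specific; the toy fixture supplies one.

At sub-maximal μ the feasibility system is degenerate (any sufficiently
large ribosome pool is admissible), so quantities reported along a growth
sweep — notably the ribosome-to-protein mass fraction — are evaluated at
the *minimal-proteome* solution of each μ, i.e. minimizing the tracked
`proteome_capacity` value; that is the resource-parsimonious proteome the
formulation is about.

`communityConstraints()` concatenates abundance-weighted members under
`members/<id>` (per-member fluxes are per gDW of that member), creates one
community exchange variable per declared exchange
(`x_e = Σ_m a_m v_{m,e}`, per gDW of total community) carrying the
environment bound, and ties every member's growth value to a single
community growth variable μ (balanced exponential growth).  Abundances are
fixed per solve; growth-maximizing compositions are found by scanning the
simplex (`compositionScreen()`), with exact rational lattice points
(`simplexGrid()`) to avoid floating drift.  Whether abundances could
instead be embedded as variables was left open by the source formulation;
scanning plus (where needed) bisection reproduces the same observable and
keeps every solve linear.

# Analysis layer

* `fluxBalanceAnalysis()` — one LP, maximizing a tracked value.
* `parsimoniousAnalysis()` — stage 1 finds the optimum Z, stage 2 floors
  the objective at γZ (γ defaults to 1−1e−6, exposed as an argument),
  splits every flux leaf `v = v⁺ − v⁻` and minimizes `Σ(v⁺+v⁻)`.
* `fluxVariability()` — per-target min/max above the γ floor; each solve
  is independent and from scratch (determinism over speed at these sizes);
  per-target failures are recorded in the result, not fatal.
* `productionEnvelope()` — one or two tracked quantities re-bound to
  `EqualTo` over a grid, objective maximized and minimized, infeasible
  points marked.
* `growthBisection()` — outer search for systems linear only at fixed μ.
  Requires monotone feasibility; returns the *lower* bracket end, i.e. the
  largest μ actually verified feasible, never an unverified midpoint.

# Numerical choices

* LP backend: a dense two-phase primal simplex with Bland's rule.  Bland
  guarantees finite termination and bit-level determinism; its slower
  pivoting is irrelevant at desk scale (tens to a few hundred variables).
  Free variables are split `x = x⁺ − x⁻`.
* Rows are max-norm equilibrated before solving; the final basic solution
  is recomputed from the equilibrated data rather than the pivoted
  tableau, so accumulated drift cannot leak into results.
* Phase-1 feasibility threshold: `1e-10·(1+max|b|)` on equilibrated data —
  a genuinely feasible system terminates with roundoff-level residual, so
  anything above is classified infeasible.
* Every optimal point is audited row-wise at `1e-9 + 1e-6·|bound|`; an
  audit failure is reported as status `"failed"`, distinct from
  infeasible/unbounded.  During bisection, such knife-edge solves are
  conservatively treated as infeasible, which keeps the returned growth
  rate verified-feasible.
* The pFBA/FVA objective floor is relaxed by `1e-9·(1+|floor|)` so the
  stage-1 optimum itself remains feasible under finite solver tolerance.
* `lpVertexOracle()` — the test oracle — shares no code with the simplex:
  it enumerates basic points from all hyperplane subsets inside a 1e7 box
  and detects unboundedness by re-solving with a 100× box.  It assumes
  problem data far below the box and refuses instances it cannot enumerate.

# What the toy fixtures emulate — and what they do not

The fixtures are first-class, deterministic generators with hand-derived
optima: a linear chain (optimum = uptake bound), a diamond with a redundant
parallel path (flux variability and parsimony behavior), a chain with a
competing drain (linear growth/byproduct trade-off), a single-substrate
enzyme+ribosome model (layered capacity effects), and a mutually
auxotrophic pair whose enzyme-constrained composition optimum is asymmetric
by construction (`mu = min(5·a₁, 20·a₂)`, maximal at a₁ = 0.8).  They
exercise every code path of the builders and analyses with analytically
checkable answers.

They do not emulate genome-scale properties: thousands of reactions,
redundant pathway structure at scale, realistic kcat distributions,
thermodynamic constraints, or measured proteome budgets.  Passing tests
demonstrate correctness of the constraint assembly and of the optimization
machinery, not predictive accuracy on real organisms — applying the same
builders to a curated genome-scale model with measured kinetics is the
intended use but requires those external inputs.

# Known limitations

* LP only — no QP/MILP, no flux sampling, no loopless constraints.
* The simplex is dense and sequential; it targets correctness and
  determinism, not genome-scale speed.
* SBML input covers the core FBC subset (species, reactions, bounds via
  flux-bound parameters, gene associations, first active objective);
  annotations and other SBML packages are ignored, and SBML is not
  written.
* The resource-balance layer models one average ribosome and no RNA
  species; capacity sectors are limited to the groups supplied in the
  kinetics table.

# Problem sizes used in the test suite

Tests and the acceptance script run LPs of 2–10 variables (random
solver-vs-oracle cross-checks), fixture systems of 3–5 reactions, a
two-member community screen on an 11-point simplex grid, and growth
bisections to tolerances of 1e-4 to 1e-6 — sizes chosen so the entire
suite re-derives every expected number from scratch in well under a
minute per file.
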