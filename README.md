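# fluxtree

Modular construction and analysis of constraint-based metabolic models in R,
built around *constraint trees*: directory-like hierarchies whose leaves bind
sparse linear expressions over a shared variable space to equality or
interval bounds.

## Why

Constraint-based models predict cellular physiology from reaction
stoichiometry by linear optimization.  The base formulation, flux balance
analysis (FBA), solves

```
max  c' v
s.t. S v = 0,   lb <= v <= ub
```

where `S` is the stoichiometric matrix and `v` the flux vector
(mmol gDW⁻¹ h⁻¹).  Realistic extensions pile further linear systems on top:

* **ec-FBA** (enzyme-constrained, GECKO-style): directional isozyme fluxes
  `w_{r,i,d} >= 0` coupled to net fluxes, enzyme demands
  `g_p = Σ n_{p,i} (w_fwd/kcat_fwd + w_rev/kcat_rev)`, and proteome-sector
  capacities `Σ mw_p g_p <= limit`.
* **sRBA** (simplified resource balance): ribosome kinetics and capacity
  `Σ L_p s_p + L_R μ R <= k_t R`, growth dilution `s_p = μ g_p`,
  polymerization ATP costs, and a total proteome budget — linear at a fixed
  growth rate `μ`, with the maximal feasible `μ` recovered by bisection.
* **cFBA / ec-cFBA** (communities): abundance-weighted members sharing an
  exchange pool, `x_e = Σ_m a_m v_{m,e}`, growing at one common rate.

Writing such stacks directly against one big matrix means fragile index
bookkeeping.  Here every layer is an independent building block that returns
a labeled tree; trees combine with automatic variable renumbering
(`combineIndependent()`), overlay over a shared variable space
(`mergeShared()`), are addressed by path (`tree[["fluxes/r1"]]`), and
solutions come back in the very same shape (`solutionTree()`).

## Worked example

```r
library(fluxtree)

bundle <- toyDiamondModel()            # A -> B through two parallel paths
tree   <- fluxBalanceConstraints(bundle@model)
tree
#> ConstraintTree: 3 top-level entries, 4 variables
#>   fluxes/ (4 entries)
#>     r_in: 1*x1 in [0, 10]
#>     r1: 1*x2 in [0, Inf]
#>     r2: 1*x3 in [0, Inf]
#>     r_out: 1*x4 in [0, Inf]
#>   flux_stoichiometry/ (2 entries)
#>     A: 1*x1 - 1*x2 - 1*x3 = 0
#>     B: 1*x2 + 1*x3 - 1*x4 = 0
#>   objective: 1*x4 (tracked)

res <- parsimoniousAnalysis(tree)      # two-stage pFBA
res$objective                          # 10   (uptake bound is the bottleneck)
res$totalFlux                          # 30   (10 in + 10 across + 10 out)
res$solution$fluxes
#> $r_in 10; $r1 10; $r2 0; $r_out 10   (one parallel path idles)
```

The objective 10 is the FBA optimum (the uptake bound); the parsimonious
stage then finds the smallest total flux, 30, that still attains it, idling
one of the two redundant paths.

Community screens work the same way.  The built-in cross-feeding pair —
two auxotrophic members that each synthesize one metabolite both need —
only grows as a pair, and its enzyme-constrained optimum sits at an
asymmetric composition because the two synthesis enzymes differ in turnover
number (5 vs 20 h⁻¹):

```r
pair <- toyCrossfeedPair()
scr  <- compositionScreen(crossfeedSpec(pair), k = 10)
scr[6:10, ]
#>     m1  m2  mu
#> 6  0.5 0.5 2.5
#> 7  0.6 0.4 3.0
#> 8  0.7 0.3 3.5
#> 9  0.8 0.2 4.0   <- growth-maximizing composition
#> 10 0.9 0.1 2.0
```

The slow producer (member 1) must make up 80 % of the biomass; the
community growth rate `mu = min(5 a1, 20 a2)` peaks at exactly 4 h⁻¹.

A command-line interface wraps the same functions
(`exec/fluxtree fba --model model.json`, plus `pfba`, `fva`, `envelope`,
`community`, `srba`, and `fixture` to materialize the toy models as COBRA
JSON).

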