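#' Bundle a synthetic model with its known optimum
#' @param model,kinetics,srba,analyticOptimum,description slots; see
#'   [FixtureBundle-class].
#' @return a [FixtureBundle-class].
#' @export
fixtureBundle <- function(model, kinetics = NULL, srba = NULL,
                          analyticOptimum = NA_real_, description = "") {
  new("FixtureBundle", model = model, kinetics = kinetics, srba = srba,
      analyticOptimum = analyticOptimum, description = description)
}

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle:", object@description, "\n")
  if (!is.na(object@analyticOptimum))
    cat("  analytic optimum:", object@analyticOptimum, "\n")
})

#' Linear chain toy model
#'
#' Two metabolites A, B; reactions `r_in` (uptake, `[0, uMax]`), `r_conv`
#' (A -> B, `[0, Inf)`) and `r_growth` (drain of B, objective).  The single
#' bottleneck makes the FBA optimum exactly `uMax`.  `r_conv` carries the
#' GPR rule `g1`, so knocking out `g1` is lethal.
#'
#' @param uMax uptake bound (mmol/gDW/h, `>= 0`).
#' @return a [FixtureBundle-class].
#' @export
toyChainModel <- function(uMax = 10) {
  if (length(uMax) != 1L || is.na(uMax) || uMax < 0)
    stop("uMax must be a single non-negative number")
  model <- canonicalModel(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("r_in", "r_conv", "r_growth"),
      lower = c(0, 0, 0), upper = c(uMax, Inf, Inf),
      objective = c(0, 0, 1)),
    stoichiometry = list(r_in = c(A = 1), r_conv = c(A = -1, B = 1),
                         r_growth = c(B = -1)),
    gprs = list(r_conv = "g1"), genes = "g1")
  fixtureBundle(model, analyticOptimum = uMax,
                description = sprintf("linear chain, uptake <= %g", uMax))
}

#' Diamond toy model with a parallel path
#'
#' `r_in` (`[0, 10]`) feeds A; `r1` and `r2` both convert A -> B; `r_out`
#' drains B (objective).  Optimum 10; at the optimum `r1 + r2 = 10` with the
#' split free, so FVA at `gamma = 1` gives `r1` in `[0, 10]` and
#' parsimonious FBA totals `|v| = 30` (10 in, 10 across, 10 out).
#'
#' @return a [FixtureBundle-class].
#' @export
toyDiamondModel <- function() {
  model <- canonicalModel(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("r_in", "r1", "r2", "r_out"),
      lower = c(0, 0, 0, 0), upper = c(10, Inf, Inf, Inf),
      objective = c(0, 0, 0, 1)),
    stoichiometry = list(r_in = c(A = 1), r1 = c(A = -1, B = 1),
                         r2 = c(A = -1, B = 1), r_out = c(B = -1)))
  fixtureBundle(model, analyticOptimum = 10,
                description = "diamond: parallel A->B paths")
}

#' Chain with a competing byproduct drain
#'
#' The linear chain plus `r_drain` (A -> nothing, `[0, Inf)`): every unit of
#' forced drain costs one unit of growth, so the envelope over the drain is
#' `max objective = 10 - p` for `p` in `[0, 10]` and infeasible beyond.
#'
#' @return a [FixtureBundle-class].
#' @export
toyTradeoffModel <- function() {
  model <- canonicalModel(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(
      id = c("r_in", "r_conv", "r_drain", "r_growth"),
      lower = c(0, 0, 0, 0), upper = c(10, Inf, Inf, Inf),
      objective = c(0, 0, 0, 1)),
    stoichiometry = list(r_in = c(A = 1), r_conv = c(A = -1, B = 1),
                         r_drain = c(A = -1), r_growth = c(B = -1)))
  fixtureBundle(model, analyticOptimum = 10,
                description = "chain with byproduct drain (envelope fixture)")
}

#' Enzyme-constrained fixture for the sRBA layer
#'
#' Single-substrate model with explicit energy metabolites: `r_upt` imports
#' S (`[0, 10]`), `r_cat` (gene `e1`) converts S + 2 ADP + 2 Pi into 2 ATP,
#' `r_growth` (gene `e2`) drains S as biomass (objective).  Kinetics give
#' both enzymes turnover numbers, masses and lengths; the ATP produced by
#' `r_cat` pays the polymerization cost added by [srbaConstraints()].
#'
#' @return a [FixtureBundle-class] with kinetics and [srbaParams()] attached
#'   (ATP hydrolysis mapped to `ATP`/`ADP`/`Pi`).
#' @export
toySrbaModel <- function() {
  model <- canonicalModel(
    metabolites = data.frame(id = c("S", "ATP", "ADP", "Pi"), compartment = "c"),
    reactions = data.frame(
      id = c("r_upt", "r_cat", "r_growth"),
      lower = c(0, 0, 0), upper = c(10, Inf, Inf),
      objective = c(0, 0, 1)),
    stoichiometry = list(
      r_upt = c(S = 1),
      r_cat = c(S = -1, ADP = -2, Pi = -2, ATP = 2),
      r_growth = c(S = -1)),
    gprs = list(r_cat = "e1", r_growth = "e2"), genes = c("e1", "e2"))
  kin <- kineticsTable(
    isozymes = list(
      r_cat = list(isozyme(c(e1 = 1), kcatFwd = 50)),
      r_growth = list(isozyme(c(e2 = 1), kcatFwd = 10))),
    masses = c(e1 = 40, e2 = 40),
    lengths = c(e1 = 364, e2 = 364),
    capacities = list(all = list(genes = "all", limit = 0.55)))
  srba <- srbaParams(atpHydrolysis = c(ATP = -1, ADP = 1, Pi = 1))
  fixtureBundle(model, kinetics = kin, srba = srba,
                description = "single-substrate enzyme + ribosome fixture")
}

#' Mutually auxotrophic cross-feeding pair
#'
#' Two members that each synthesize one of two metabolites both need for
#' growth: member `m1` makes `M1` (gene `s1`), member `m2` makes `M2` (gene
#' `s2`); each grows only by importing the other's product through the
#' shared exchange pool, which the environment keeps closed (`EqualTo(0)`).
#' Alone, either member cannot grow; together they cross-feed.  The two
#' synthesis enzymes differ in turnover (`s1`: 5/h, `s2`: 20/h; masses 1
#' g/mmol, capacity 1 g/gDW), so under enzyme constraints the
#' growth-maximizing composition is asymmetric: `mu* = min(5 a1, 20 a2)`,
#' maximal at `a1 = 0.8` with `mu* = 4`.  Without enzyme constraints the
#' synthesis bound (1000) is far from binding and the surface is set by the
#' exchange balances alone, peaking at the symmetric composition.
#'
#' @return list with `models` (named [CanonicalModel-class]s), `kinetics`
#'   (named [KineticsTable-class]s), `exchanges` (per member: exchange id ->
#'   member tree path), `environment` (closed `M1`/`M2` pool bounds), and
#'   `analytic` (list with `argmax` and `muMax` of the enzyme-constrained
#'   screen).
#' @seealso [crossfeedSpec()]
#' @export
toyCrossfeedPair <- function() {
  member <- function(own, gene) {
    other <- setdiff(c("M1", "M2"), own)
    canonicalModel(
      metabolites = data.frame(id = c("M1", "M2"), compartment = "c"),
      reactions = data.frame(
        id = c(paste0("syn_", own), "ex_M1", "ex_M2", "r_growth"),
        lower = c(0, -Inf, -Inf, 0), upper = c(1000, Inf, Inf, Inf),
        objective = c(0, 0, 0, 1)),
      stoichiometry = stats::setNames(
        list(stats::setNames(1, own), c(M1 = -1), c(M2 = -1),
             c(M1 = -1, M2 = -1)),
        c(paste0("syn_", own), "ex_M1", "ex_M2", "r_growth")),
      gprs = stats::setNames(list(gene), paste0("syn_", own)),
      genes = gene)
  }
  kin <- function(own, gene, kcat) kineticsTable(
    isozymes = stats::setNames(list(list(isozyme(stats::setNames(1, gene),
                                                 kcatFwd = kcat))),
                               paste0("syn_", own)),
    masses = stats::setNames(1, gene),
    lengths = stats::setNames(300L, gene),
    capacities = list(all = list(genes = "all", limit = 1)))
  list(
    models = list(m1 = member("M1", "s1"), m2 = member("M2", "s2")),
    kinetics = list(m1 = kin("M1", "s1", 5), m2 = kin("M2", "s2", 20)),
    exchanges = list(m1 = c(M1 = "fluxes/ex_M1", M2 = "fluxes/ex_M2"),
                     m2 = c(M1 = "fluxes/ex_M1", M2 = "fluxes/ex_M2")),
    environment = list(M1 = equalTo(0), M2 = equalTo(0)),
    analytic = list(argmax = c(m1 = 0.8, m2 = 0.2), muMax = 4))
}

#' Community specification for the cross-feeding pair
#'
#' @param pair result of [toyCrossfeedPair()].
#' @param abundances named abundances (default symmetric).
#' @param enzymes apply each member's enzyme constraints (`TRUE`) or use the
#'   plain flux systems (`FALSE`).
#' @return a [CommunitySpec-class].
#' @export
crossfeedSpec <- function(pair, abundances = c(m1 = 0.5, m2 = 0.5),
                          enzymes = TRUE) {
  members <- lapply(names(pair$models), function(id) {
    tree <- fluxBalanceConstraints(pair$models[[id]])
    if (enzymes)
      tree <- enzymeConstraints(tree, pair$models[[id]], pair$kinetics[[id]])
    communityMember(id, tree, pair$exchanges[[id]])
  })
  communitySpec(members, abundances, pair$environment)
}
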