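# shared fixture: parallel A->B paths with distinct enzymes
parallelEcFixture <- function(capacity = 1) {
  model <- canonicalModel(
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = c("r_in", "rA", "rB", "r_out"),
                           lower = 0, upper = Inf, objective = c(0, 0, 0, 1)),
    stoichiometry = list(r_in = c(A = 1), rA = c(A = -1, B = 1),
                         rB = c(A = -1, B = 1), r_out = c(B = -1)),
    gprs = list(rA = "gA", rB = "gB"), genes = c("gA", "gB"))
  kinetics <- kineticsTable(
    isozymes = list(rA = list(isozyme(c(gA = 1), kcatFwd = 10)),
                    rB = list(isozyme(c(gB = 1), kcatFwd = 5))),
    masses = c(gA = 1, gB = 1), lengths = c(gA = 300L, gB = 300L),
    capacities = list(all = list(genes = "all", limit = capacity)))
  list(model = model, kinetics = kinetics)
}

test_that("fluxBalanceConstraints lays out fluxes, balances and objective", {
  model <- toyChainModel(10)@model
  tree <- fluxBalanceConstraints(model)
  expect_setequal(names(tree@children),
                  c("fluxes", "flux_stoichiometry", "objective"))
  # balance row for A reads the stoichiometry: v_in - v_conv = 0
  a <- accessPath(tree, "flux_stoichiometry/A")
  expect_equal(a@value@idx, c(1L, 2L))
  expect_equal(a@value@coef, c(1, -1))
  expect_s4_class(bound(a), "EqualToBound")
  expect_equal(bound(a)@value, 0)
  expect_s4_class(bound(accessPath(tree, "objective")), "AbsentBound")
  # row count: one per metabolite plus one per reaction
  expect_equal(length(flattenTree(tree)@paths),
               nrow(metabolites(model)) + nrow(reactions(model)))

  empty <- canonicalModel(
    metabolites = data.frame(id = character(0), compartment = character(0)),
    reactions = data.frame(id = character(0), lower = numeric(0),
                           upper = numeric(0), objective = numeric(0)))
  et <- fluxBalanceConstraints(empty)
  expect_equal(length(et$fluxes@children), 0L)
  expect_equal(length(et$flux_stoichiometry@children), 0L)
})

test_that("knockout zeroes exactly the reactions whose rule dies", {
  bundle <- toyChainModel(10)
  tree <- fluxBalanceConstraints(bundle@model)
  expect_equal(knockout(tree, bundle@model, character(0)), tree)
  ko <- knockout(tree, bundle@model, "g1")
  expect_equal(fluxBalanceAnalysis(ko)$objective, 0, tolerance = 1e-9)
  # isozyme rule survives single knockout
  m2 <- oneReactionModel("g1 or g2", c("g1", "g2"))
  t2 <- fluxBalanceConstraints(m2)
  expect_equal(knockout(t2, m2, "g1"), t2)
  expect_equal(fluxBalanceAnalysis(knockout(t2, m2, c("g1", "g2")))$objective,
               0, tolerance = 1e-9)
  expect_warning(knockout(tree, bundle@model, "nosuchgene"), "unknown gene")
})

test_that("knockout is idempotent and order-independent over gene sets", {
  m <- oneReactionModel("g1 and (g2 or g3)", c("g1", "g2", "g3"))
  t <- fluxBalanceConstraints(m)
  k1 <- knockout(t, m, c("g2", "g3"))
  k2 <- knockout(t, m, c("g3", "g2"))
  expect_equal(flattenTree(k1), flattenTree(k2))
  expect_equal(knockout(k1, m, c("g2", "g3")), k1)       # idempotent
  expect_equal(knockout(knockout(t, m, "g1"), m, "g1"),
               knockout(t, m, "g1"))
})

test_that("random GPRs force-zero a reaction iff the rule evaluates false", {
  set.seed(55)
  for (i in 1:15) {
    gpr <- randomGpr()
    m <- oneReactionModel(gpr, paste0("g", 1:6))
    t <- fluxBalanceConstraints(m)
    ko <- sample(paste0("g", 1:6), sample(0:5, 1L))
    kt <- knockout(t, m, ko)
    b <- bound(accessPath(kt, "fluxes/r_out"))
    if (evalGpr(gpr, ko)) expect_s4_class(b, "BetweenBound")
    else {
      expect_s4_class(b, "EqualToBound")
      expect_equal(b@value, 0)
    }
  }
})

test_that("enzyme constraints reproduce the analytic capacity optimum", {
  fx <- parallelEcFixture(1)
  tree <- enzymeConstraints(fluxBalanceConstraints(fx$model), fx$model,
                            fx$kinetics)
  expect_setequal(setdiff(names(tree@children),
                          c("fluxes", "flux_stoichiometry", "objective")),
                  c("isozyme_fluxes", "directional_coupling",
                    "gene_product_amounts", "capacity"))
  # fastest enzyme saturates the shared capacity: 10/h * 1 mmol/gDW
  expect_equal(fluxBalanceAnalysis(tree)$objective, 10, tolerance = 1e-8)
  # solution wiring: gene amounts follow w/kcat
  sol <- fluxBalanceAnalysis(tree)$solution
  expect_equal(sol$gene_product_amounts$gA,
               sol$isozyme_fluxes$rA$iso1$fwd / 10, tolerance = 1e-8)
})

test_that("ec optimum is homogeneous in the capacity limits", {
  fx1 <- parallelEcFixture(1); fx2 <- parallelEcFixture(2)
  z1 <- fluxBalanceAnalysis(enzymeConstraints(fluxBalanceConstraints(fx1$model),
                                              fx1$model, fx1$kinetics))$objective
  z2 <- fluxBalanceAnalysis(enzymeConstraints(fluxBalanceConstraints(fx2$model),
                                              fx2$model, fx2$kinetics))$objective
  expect_equal(z2, 2 * z1, tolerance = 1e-6)
})

test_that("enzyme constraints validate kinetics and spare uncovered leaves", {
  fx <- parallelEcFixture(1)
  base <- fluxBalanceConstraints(fx$model)
  tree <- enzymeConstraints(base, fx$model, fx$kinetics)
  # r_in has no kinetics: its flux leaf is untouched
  expect_identical(accessPath(tree, "fluxes/r_in"), accessPath(base, "fluxes/r_in"))
  # open direction without a kcat errors
  kinNoFwd <- kineticsTable(
    isozymes = list(rA = list(isozyme(c(gA = 1), kcatRev = 5))),
    masses = c(gA = 1), lengths = c(gA = 300L))
  expect_error(enzymeConstraints(base, fx$model, kinNoFwd), "lacks kcat_fwd")
  expect_error(isozyme(c(gA = 1), kcatFwd = -1), "positive")
  kinGhost <- kineticsTable(isozymes = list(ghost = list(isozyme(c(gA = 1), kcatFwd = 1))))
  expect_error(enzymeConstraints(base, fx$model, kinGhost), "unknown reaction")
})

test_that("reversible reactions split into directional isozyme fluxes", {
  model <- canonicalModel(
    metabolites = data.frame(id = "A", compartment = "c"),
    reactions = data.frame(id = c("r_in", "r_rev"), lower = c(-5, -10),
                           upper = c(5, 10), objective = c(0, 0)),
    stoichiometry = list(r_in = c(A = 1), r_rev = c(A = -1)),
    gprs = list(r_rev = "g"), genes = "g")
  kin <- kineticsTable(
    isozymes = list(r_rev = list(isozyme(c(g = 1), kcatFwd = 10, kcatRev = 4))),
    masses = c(g = 1), lengths = c(g = 100L),
    capacities = list(all = list(genes = "all", limit = 1)))
  tree <- enzymeConstraints(fluxBalanceConstraints(model), model, kin)
  expect_s4_class(accessPath(tree, "isozyme_fluxes/r_rev/iso1/fwd"), "Constraint")
  expect_s4_class(accessPath(tree, "isozyme_fluxes/r_rev/iso1/rev"), "Constraint")
  # reverse flux costs 1/kcat_rev enzyme: min g at forced reverse flux 2 is 0.5
  t2 <- replaceAt(tree, "fluxes/r_rev",
                  constraint(value(accessPath(tree, "fluxes/r_rev")), equalTo(-2)))
  out <- optimizeTree(t2, value(accessPath(t2, "gene_product_amounts/g")), "min")
  expect_equal(out@objectiveValue, 0.5, tolerance = 1e-8)
})

test_that("constraint layers only tighten the growth optimum", {
  s <- toySrbaModel()
  base <- fluxBalanceConstraints(s@model)
  fba <- fluxBalanceAnalysis(base)$objective
  ec <- enzymeConstraints(base, s@model, s@kinetics)
  ecOpt <- fluxBalanceAnalysis(ec)$objective
  mu <- growthBisection(function(m)
    srbaConstraints(ec, s@model, s@kinetics, s@srba, m),
    lo = 0, hi = ecOpt + 1, tol = 1e-5)
  expect_gte(fba, ecOpt - 1e-9)
  expect_gte(ecOpt, mu - 1e-9)
  expect_gt(mu, 0)
})

test_that("the resource balance layer is consistent at zero growth", {
  s <- toySrbaModel()
  ec <- enzymeConstraints(fluxBalanceConstraints(s@model), s@model, s@kinetics)
  t0 <- srbaConstraints(ec, s@model, s@kinetics, s@srba, 0)
  out <- optimizeTree(t0, value(accessPath(t0, "proteome_capacity")), "min")
  expect_equal(out@status, "optimal")
  sol <- solutionTree(t0, out@assignment)
  expect_equal(sol$ribosome, 0, tolerance = 1e-9)
  expect_true(all(abs(unlist(sol$protein_synthesis)) < 1e-9))
  # ordering requirement
  expect_error(srbaConstraints(fluxBalanceConstraints(s@model), s@model,
                               s@kinetics, s@srba, 0.1),
               "enzymeConstraints")
  kinShort <- s@kinetics
  kinShort@lengths <- kinShort@lengths["e1"]
  expect_error(srbaConstraints(ec, s@model, kinShort, s@srba, 0.1),
               "missing protein length")
})

test_that("layering preserves pre-existing leaf values except ATP amendments", {
  s <- toySrbaModel()
  base <- fluxBalanceConstraints(s@model)
  ec <- enzymeConstraints(base, s@model, s@kinetics)
  for (p in leafPaths(base))
    expect_equal(value(accessPath(ec, p)), value(accessPath(base, p)))
  tr <- srbaConstraints(ec, s@model, s@kinetics, s@srba, 0.02)
  amended <- paste0("flux_stoichiometry/", names(s@srba@atpHydrolysis))
  untouched <- setdiff(leafPaths(ec), c(amended, "objective"))
  for (p in untouched)
    expect_equal(value(accessPath(tr, p)), value(accessPath(ec, p)))
})
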