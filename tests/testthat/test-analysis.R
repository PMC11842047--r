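test_that("FBA matches the oracle and respects closed uptake", {
  tree <- fluxBalanceConstraints(toyChainModel(10)@model)
  r <- fluxBalanceAnalysis(tree)
  o <- lpVertexOracle(flattenTree(tree), value(accessPath(tree, "objective")), "max")
  expect_equal(r$objective, o$value, tolerance = 1e-6)
  expect_equal(fluxBalanceAnalysis(
    fluxBalanceConstraints(toyChainModel(0)@model))$objective, 0,
    tolerance = 1e-9)
  b <- toyChainModel(10)
  ko <- knockout(fluxBalanceConstraints(b@model), b@model, "g1")
  rk <- fluxBalanceAnalysis(ko)
  expect_true(rk$status != "optimal" || rk$objective <= 1e-9)
})

test_that("parsimonious FBA minimizes total flux at near-optimal objective", {
  tree <- fluxBalanceConstraints(toyDiamondModel()@model)
  p <- parsimoniousAnalysis(tree)
  expect_equal(p$status, "optimal")
  expect_gte(p$objective, 10 * (1 - 1e-6) - 1e-6)
  expect_equal(p$totalFlux, 30, tolerance = 1e-4)
  # pFBA L1 norm never exceeds the FBA solution's
  f <- fluxBalanceAnalysis(tree)
  l1 <- function(sol) sum(abs(unlist(sol$fluxes)))
  expect_lte(p$totalFlux, l1(f$solution) + 1e-6)
  # solution satisfies the original constraints
  flat <- flattenTree(tree)
  Ax <- as.vector(flat@A %*% p$assignment)
  expect_true(all(Ax >= flat@lower - 1e-6 & Ax <= flat@upper + 1e-6))
})

test_that("pFBA equals FBA when the solution is unique, and gamma = 0 idles", {
  tree <- fluxBalanceConstraints(toyChainModel(10)@model)
  p <- parsimoniousAnalysis(tree)
  f <- fluxBalanceAnalysis(tree)
  expect_equal(unlist(p$solution$fluxes), unlist(f$solution$fluxes),
               tolerance = 1e-4)
  idle <- parsimoniousAnalysis(tree, fraction = 0)
  expect_true(all(abs(unlist(idle$solution$fluxes)) < 1e-6))
})

test_that("FVA brackets fluxes and never narrows when gamma loosens", {
  dtree <- fluxBalanceConstraints(toyDiamondModel()@model)
  fv <- fluxVariability(dtree, fraction = 1, targets = c("fluxes/r1", "fluxes/r2"))
  expect_equal(fv$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fv$max, c(10, 10), tolerance = 1e-6)

  ctree <- fluxBalanceConstraints(toyChainModel(10)@model)
  cv <- fluxVariability(ctree, fraction = 1, targets = "fluxes/r_in")
  expect_equal(cv$min, 10, tolerance = 1e-6)
  expect_equal(cv$max, 10, tolerance = 1e-6)

  # FBA solution contained in every interval; min <= max
  f <- fluxBalanceAnalysis(dtree)
  all9 <- fluxVariability(dtree, fraction = 0.9)
  tight <- fluxVariability(dtree, fraction = 1)
  for (i in seq_len(nrow(tight))) {
    v <- unlist(f$solution$fluxes)[basename(tight$path[i])]
    expect_lte(tight$min[i], tight$max[i] + 1e-9)
    expect_gte(v, tight$min[i] - 1e-6)
    expect_lte(v, tight$max[i] + 1e-6)
    expect_lte(all9$min[i], tight$min[i] + 1e-6)
    expect_gte(all9$max[i], tight$max[i] - 1e-6)
  }
})

test_that("production envelopes trace the growth/byproduct trade-off", {
  tree <- fluxBalanceConstraints(toyTradeoffModel()@model)
  env <- productionEnvelope(tree, dims = "fluxes/r_drain",
                            grids = list(c(0:10, 11)))
  feas <- env[env$feasible, ]
  expect_equal(feas[["fluxes/r_drain"]], 0:10)
  expect_equal(feas$objectiveMax, 10 - (0:10), tolerance = 1e-6)
  expect_equal(env$objectiveMax[env[["fluxes/r_drain"]] == 0], 10,
               tolerance = 1e-8)                      # p = 0 is plain FBA
  expect_false(env$feasible[env[["fluxes/r_drain"]] == 11])
  expect_true(all(diff(feas$objectiveMax) <= 1e-8))   # non-increasing
})

test_that("growth bisection recovers analytic optima of LP-wrapped builders", {
  tree <- fluxBalanceConstraints(toyChainModel(10)@model)
  gleaf <- accessPath(tree, "objective")
  builder <- function(mu) replaceAt(tree, "objective",
                                    constraint(gleaf@value, equalTo(mu)))
  mu <- growthBisection(builder, lo = 0, hi = 25, tol = 1e-4)
  expect_equal(mu, 10, tolerance = 1e-4)
  expect_equal(growthBisection(builder, lo = 0, hi = 10, tol = 1e-4), 10)
  expect_error(growthBisection(builder, lo = 11, hi = 25, tol = 1e-4),
               "infeasible")
})

test_that("simplex grids enumerate exact lattice compositions", {
  for (m in 2:3) for (k in c(1L, 4L)) {
    g <- simplexGrid(m, k)
    expect_equal(nrow(g), choose(k + m - 1, m - 1))
    expect_true(all(abs(rowSums(g) - 1) < 1e-12))
    expect_true(all(g >= 0))
  }
})

test_that("screens over identical members are flat", {
  spec <- communitySpec(
    list(communityMember("a", fluxBalanceConstraints(toyChainModel(1000)@model),
                         c(glc = "fluxes/r_in")),
         communityMember("b", fluxBalanceConstraints(toyChainModel(1000)@model),
                         c(glc = "fluxes/r_in"))),
    c(a = 0.5, b = 0.5), list(glc = between(0, 10)))
  scr <- compositionScreen(spec, 5)
  expect_equal(nrow(scr), 6L)
  expect_lte(max(scr$mu) - min(scr$mu), 1e-6)
})
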