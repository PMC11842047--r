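test_that("linear value arithmetic behaves like ordinary linear forms", {
  a <- linearValue(1, c(1, 2), c(2, 3))
  b <- linearValue(0, c(2, 4), c(1, -1))
  s <- a + b
  expect_equal(s@constant, 1)
  expect_equal(s@idx, c(1L, 2L, 4L))
  expect_equal(s@coef, c(2, 4, -1))
  expect_equal((a - a)@idx, integer(0))           # cancellation drops zeros
  expect_equal((2 * a)@coef, c(4, 6))
  expect_equal((a * 0.5)@constant, 0.5)
  expect_equal((-a)@coef, c(-2, -3))
  # commutativity / distributivity on random draws
  set.seed(11)
  for (i in 1:20) {
    u <- linearValue(runif(1), sample(6, 3), runif(3, -2, 2))
    v <- linearValue(runif(1), sample(6, 3), runif(3, -2, 2))
    s <- runif(1, -3, 3)
    expect_equal(u + v, v + u)
    lhs <- s * (u + v); rhs <- s * u + s * v
    expect_equal(lhs@constant, rhs@constant, tolerance = 1e-12)
    expect_equal(lhs@coef, rhs@coef, tolerance = 1e-12)
  }
  expect_error(a * b, "not linear")
})

test_that("substituteValue matches a dense dot-product oracle", {
  expect_equal(substituteValue(linearValue(1, 1:2, c(2, 3)), c(1, 2)), 9)
  expect_equal(substituteValue(constantValue(5), numeric(0)), 5)
  expect_error(substituteValue(variableValue(3), c(1, 2)), "too short")
  set.seed(42)
  for (i in 1:100) {
    idx <- sort(sample(12, 6))
    coef <- runif(6, -5, 5)
    cst <- runif(1, -2, 2)
    v <- linearValue(cst, idx, coef)
    x <- runif(12, -3, 3)
    dense <- numeric(12); dense[idx] <- coef
    expect_equal(substituteValue(v, x), cst + sum(dense * x), tolerance = 1e-12)
  }
})

test_that("makeVariables allocates in order and rejects bad input", {
  expect_equal(variableCount(makeVariables(character(0), list())), 0L)
  t <- makeVariables(c("a", "b"), list(between(0, 10), absentBound()))
  expect_equal(value(t[["a"]])@idx, 1L)
  expect_equal(value(t[["b"]])@idx, 2L)
  expect_s4_class(bound(t[["a"]]), "BetweenBound")
  expect_s4_class(bound(t[["b"]]), "AbsentBound")
  nested <- makeVariables(c("fluxes/r1", "fluxes/r2"), between(0, 1))
  expect_s4_class(nested$fluxes, "ConstraintTree")
  expect_equal(leafPaths(nested), c("fluxes/r1", "fluxes/r2"))
  expect_error(makeVariables(c("a", "a"), between(0, 1)), "duplicate")
  expect_error(makeVariables("bad label", between(0, 1)), "invalid label|malformed")
  expect_error(between(3, 2), "lower <= upper")
})

test_that("prefixLabel wraps without touching variables", {
  expect_equal(length(prefixLabel("m1", constraintTree())@children), 1L)
  t <- makeVariables("a", between(0, 1))
  p <- prefixLabel("f", t)
  expect_identical(accessPath(p, "f/a"), accessPath(t, "a"))
  pp <- prefixLabel("x", prefixLabel("y", t))
  expect_identical(accessPath(pp, "x/y/a"), accessPath(t, "a"))
  expect_equal(variableCount(pp), 1L)
  expect_error(prefixLabel("no/slash", t), "invalid label")
})

test_that("mergeShared unions entries and errors loudly on collisions", {
  t <- makeVariables(c("a/x", "b/y"), between(0, 1))
  expect_equal(mergeShared(t, constraintTree()), t)
  u <- mergeShared(makeVariables("a", between(0, 1)),
                   prefixLabel("b", makeVariables("c", equalTo(1))))
  expect_setequal(names(u@children), c("a", "b"))
  expect_error(mergeShared(makeVariables("a", between(0, 1)),
                           makeVariables("a", between(0, 2))),
               "collision at a")
  expect_error(mergeShared(t, makeVariables("a/x", between(0, 1))),
               "collision at a/x")
})

test_that("combineIndependent renumbers b exactly by variableCount(a)", {
  b <- makeVariables("c", between(0, 3))
  expect_equal(combineIndependent(constraintTree(), b), b)   # shift by 0
  a <- makeVariables(c("p", "q"), between(0, 1))
  ab <- combineIndependent(a, b)
  expect_equal(value(ab[["c"]])@idx, 3L)
  expect_equal(value(ab[["c"]])@coef, 1)
  expect_equal(value(ab[["p"]])@idx, 1L)                      # a untouched
  expect_equal(variableCount(ab), 3L)
  # b's flattened rows identical up to the index shift
  fb <- flattenTree(b); fab <- flattenTree(ab)
  i <- match("c", fab@paths)
  expect_equal(fab@A[i, 3], fb@A[1, 1])
  expect_equal(fab@lower[i], fb@lower[1])
  expect_error(combineIndependent(a, makeVariables("p", between(0, 1))),
               "collision")
})

test_that("tree combination is associative up to path-sorted flattening", {
  set.seed(7)
  for (rep in 1:3) {
    a <- randomSmallTree("a", 3L)
    b <- randomSmallTree("b", 2L)
    c <- randomSmallTree("c", 3L)
    f1 <- flattenTree(combineIndependent(combineIndependent(a, b), c))
    f2 <- flattenTree(combineIndependent(a, combineIndependent(b, c)))
    expect_identical(f1@paths, f2@paths)
    expect_equal(as.matrix(f1@A), as.matrix(f2@A))
    expect_equal(f1@lower, f2@lower)
    expect_equal(f1@upper, f2@upper)
  }
})

test_that("accessPath resolves paths, including the root and misses", {
  t <- makeVariables("a/b", between(0, 1))
  expect_s4_class(accessPath(t, "a/b"), "Constraint")
  expect_null(accessPath(t, "missing"))
  expect_null(accessPath(t, "a/b/c"))
  expect_identical(accessPath(t, ""), t)
  expect_identical(t[["a/b"]], accessPath(t, "a/b"))
})

test_that("replaceAt substitutes exactly one node", {
  t <- makeVariables(c("f/a", "f/b"), between(0, 10))
  leaf <- accessPath(t, "f/a")
  t2 <- replaceAt(t, "f/a", constraint(leaf@value, equalTo(0)))
  expect_s4_class(bound(accessPath(t2, "f/a")), "EqualToBound")
  expect_identical(accessPath(t2, "f/b"), accessPath(t, "f/b"))
  node <- makeVariables("z", between(0, 1))
  expect_identical(replaceAt(t, "", node), node)
  expect_error(replaceAt(t, "g/h", leaf), "missing parent")
})

test_that("mapLeaves preserves shape and reports the failing path", {
  t <- makeVariables(c("f/a", "g/b", "g/c"), between(0, 5))
  expect_equal(mapLeaves(identity, t), t)
  dropped <- mapLeaves(function(x) constraint(x@value, absentBound()), t)
  expect_equal(length(flattenTree(dropped)@paths), 0L)
  expect_identical(leafPaths(dropped), leafPaths(t))
  expect_error(mapLeaves(function(x) stop("boom"), t), "g/b|f/a")
  expect_error(mapLeaves(function(x) 42, t), "must return a Constraint")
})

test_that("solutionTree mirrors the tree shape and inverts makeVariables", {
  expect_equal(length(solutionTree(constraintTree(), numeric(0))), 0L)
  t <- makeVariables("a", between(0, 10))
  expect_equal(solutionTree(t, 3)$a, 3)
  set.seed(13)
  for (rep in 1:3) {
    tr <- randomSmallTree(paste0("t", rep), 4L)
    x <- runif(4)
    st <- solutionTree(tr, x)
    flatten <- function(l, pre = "") {
      out <- character(0)
      for (nm in names(l)) {
        p <- if (nzchar(pre)) paste(pre, nm, sep = "/") else nm
        out <- c(out, if (is.list(l[[nm]])) flatten(l[[nm]], p) else p)
      }
      out
    }
    expect_setequal(flatten(st), leafPaths(tr))
    # variable leaves read back the assignment (unlist follows insertion order)
    expect_equal(unname(unlist(st)),
                 x[vapply(leaves(tr), function(cc) cc@value@idx[1], integer(1))])
  }
  expect_error(solutionTree(t, numeric(0)), "too short")
})

test_that("variableCount is the max referenced index", {
  expect_equal(variableCount(constraintTree()), 0L)
  t <- constraintTree(list(a = constraint(variableValue(3))))
  expect_equal(variableCount(t), 3L)
  a <- makeVariables(c("a1", "a2"), between(0, 1))
  b <- makeVariables(c("b1", "b2", "b3"), between(0, 1))
  expect_equal(variableCount(combineIndependent(a, b)), 5L)
})
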