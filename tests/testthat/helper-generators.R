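# deterministic generators for property-style tests

# a small tree of fresh variables with random finite-ish bounds; top labels
# carry `tag` so several trees can be combined without collisions
randomSmallTree <- function(tag, nvars = 3L) {
  bounds <- lapply(seq_len(nvars), function(i) {
    kind <- sample(3L, 1L)
    if (kind == 1L) between(round(runif(1, -5, 0), 2), round(runif(1, 1, 6), 2))
    else if (kind == 2L) equalTo(round(runif(1, -2, 2), 2))
    else absentBound()
  })
  depth2 <- sample(c(TRUE, FALSE), nvars, replace = TRUE)
  paths <- ifelse(depth2, paste0(tag, "/sub/v", seq_len(nvars)),
                  paste0(tag, "/v", seq_len(nvars)))
  makeVariables(paths, bounds)
}

# random LP as a constraint tree: box-bounded variables plus extra rows.
# some variables get an infinite upper bound so unbounded cases occur.
randomLpTree <- function(nvars = 3L, nrows = 2L, allowInf = FALSE) {
  ub <- round(runif(nvars, 1, 5), 2)
  if (allowInf && runif(1) < 0.3) ub[sample(nvars, 1L)] <- Inf
  tree <- makeVariables(paste0("v/x", seq_len(nvars)),
                        lapply(seq_len(nvars), function(i)
                          between(round(runif(1, -4, 0), 2), ub[i])))
  rows <- constraintTree()
  for (r in seq_len(nrows)) {
    k <- sample(nvars, min(nvars, sample(1:2, 1L)))
    coefs <- sample(c(-3:-1, 1:3), length(k), replace = TRUE)
    v <- linearValue(0, k, coefs)
    b <- if (runif(1) < 0.25) equalTo(round(runif(1, -1, 1), 1))
         else between(-Inf, round(runif(1, 0, 6), 1))
    rows@children[[paste0("r", r)]] <- constraint(v, b)
  }
  tree <- mergeShared(tree, prefixLabel("rows", rows))
  obj <- linearValue(0, seq_len(nvars),
                     round(runif(nvars, -2, 2), 1))
  list(tree = tree, objective = obj)
}

randomGpr <- function(depth = 3L, genes = paste0("g", 1:6)) {
  if (depth == 0L || runif(1) < 0.4)
    return(new("GprLeaf", gene = sample(genes, 1L)))
  kids <- lapply(seq_len(sample(2:3, 1L)), function(i)
    randomGpr(depth - 1L, genes))
  if (runif(1) < 0.5) new("GprAnd", children = kids)
  else new("GprOr", children = kids)
}

# tiny inline model: one reaction with a configurable GPR
oneReactionModel <- function(gpr, genes) {
  canonicalModel(
    metabolites = data.frame(id = "A", compartment = "c"),
    reactions = data.frame(id = c("r_in", "r_out"),
                           lower = c(0, 0), upper = c(5, Inf),
                           objective = c(0, 1)),
    stoichiometry = list(r_in = c(A = 1), r_out = c(A = -1)),
    gprs = list(r_out = gpr), genes = genes)
}

expect_statusValue <- function(outcome, oracle, tol = 1e-6) {
  if (oracle$status == "optimal") {
    expect_equal(outcome@status, "optimal")
    expect_equal(outcome@objectiveValue, oracle$value, tolerance = tol)
  } else {
    expect_equal(outcome@status, oracle$status)
  }
}
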