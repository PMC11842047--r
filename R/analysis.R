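.objectiveValueAt <- function(tree, path) {
  leaf <- accessPath(tree, path)
  if (is.null(leaf) || !is(leaf, "Constraint"))
    stop(sprintf("objective path '%s' not found or not a leaf", path))
  leaf@value
}

#' Flux balance analysis on a constraint tree
#'
#' Maximizes the tracked value at `objective` and evaluates the whole tree
#' at the optimum.
#'
#' @param tree a [ConstraintTree-class].
#' @param objective path of the tracked objective leaf.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failed"`), `objective` (attained value, `NA` unless optimal),
#'   `solution` (nested value list from [solutionTree()], `NULL` unless
#'   optimal) and `assignment` (raw variable vector).
#' @examples
#' b <- toyChainModel(10)
#' fluxBalanceAnalysis(fluxBalanceConstraints(b@model))$objective   # 10
#' @export
fluxBalanceAnalysis <- function(tree, objective = "objective") {
  obj <- .objectiveValueAt(tree, objective)
  out <- optimizeTree(tree, obj, "max")
  if (out@status != "optimal")
    return(list(status = out@status, objective = NA_real_, solution = NULL,
                assignment = numeric(0)))
  list(status = "optimal", objective = out@objectiveValue,
       solution = solutionTree(tree, out@assignment),
       assignment = out@assignment)
}

.fluxLeafPaths <- function(tree, component = "fluxes") {
  paths <- leafPaths(tree)
  keep <- vapply(strsplit(paths, "/", fixed = TRUE),
                 function(p) component %in% p, logical(1))
  paths[keep]
}

.withObjectiveFloor <- function(tree, objValue, floor) {
  ## numeric guard: relax the floor by a hair so the stage-1 optimum itself
  ## stays feasible under finite solver tolerance
  slack <- 1e-9 * (1 + abs(floor))
  mergeShared(tree, constraintTree(list(
    objective_floor = constraint(objValue, between(floor - slack, Inf)))))
}

#' Parsimonious FBA
#'
#' Two-stage analysis: stage 1 finds the optimum `Z` of the tracked
#' objective; stage 2 constrains the objective to at least `fraction * Z`,
#' splits every flux leaf `v = v+ - v-` (`v+, v- >= 0`) and minimizes the
#' total absolute flux `sum(v+ + v-)`.  The returned solution satisfies the
#' original constraints and the objective floor.
#'
#' @param tree a [ConstraintTree-class].
#' @param objective path of the tracked objective leaf.
#' @param fraction objective floor fraction `gamma` (default `1 - 1e-6`).
#' @param fluxComponent label identifying flux subtrees; every leaf whose
#'   path contains this component is split (so community members' fluxes are
#'   included).
#' @return list with `status`, `objective`, `totalFlux` (the minimized L1
#'   norm), `solution` and `assignment` (both for the original tree).
#' @export
parsimoniousAnalysis <- function(tree, objective = "objective",
                                 fraction = 1 - 1e-6,
                                 fluxComponent = "fluxes") {
  obj <- .objectiveValueAt(tree, objective)
  s1 <- optimizeTree(tree, obj, "max")
  if (s1@status != "optimal")
    return(list(status = s1@status, objective = NA_real_,
                totalFlux = NA_real_, solution = NULL, assignment = numeric(0)))
  Z <- s1@objectiveValue
  t2 <- .withObjectiveFloor(tree, obj, fraction * Z)
  fpaths <- .fluxLeafPaths(tree, fluxComponent)
  n0 <- variableCount(t2)
  labs <- gsub("/", "__", fpaths)
  if (length(fpaths)) {
    block <- makeVariables(
      c(paste0("parsimonious/pos/", labs), paste0("parsimonious/neg/", labs)),
      between(0, Inf))
    t2 <- combineIndependent(t2, block)
    split <- constraintTree()
    tot <- constantValue(0)
    for (i in seq_along(fpaths)) {
      vpos <- variableValue(n0 + i)
      vneg <- variableValue(n0 + length(fpaths) + i)
      v <- accessPath(tree, fpaths[[i]])@value
      split@children[[labs[[i]]]] <- constraint(v - vpos + vneg, equalTo(0))
      tot <- tot + vpos + vneg
    }
    t2 <- mergeShared(t2, prefixLabel("parsimonious_split",
                                      prefixLabel("rows", split)))
    s2 <- optimizeTree(t2, tot, "min")
  } else s2 <- optimizeTree(t2, constantValue(0), "min")
  if (s2@status != "optimal")
    return(list(status = s2@status, objective = NA_real_,
                totalFlux = NA_real_, solution = NULL, assignment = numeric(0)))
  asg <- s2@assignment[seq_len(variableCount(tree))]
  list(status = "optimal", objective = substituteValue(obj, asg),
       totalFlux = s2@objectiveValue,
       solution = solutionTree(tree, asg), assignment = asg)
}

#' Flux variability analysis
#'
#' For each target leaf, minimizes and maximizes its value subject to the
#' tracked objective staying at or above `fraction` of its optimum.
#' Per-target solver failures are recorded in the result, not fatal.
#'
#' @param tree a [ConstraintTree-class].
#' @param objective path of the tracked objective leaf.
#' @param fraction objective floor fraction (default 1).
#' @param targets character vector of leaf paths; default: all flux leaves.
#' @return data.frame with columns `path`, `min`, `max`, `statusMin`,
#'   `statusMax` (`min`/`max` are `NA` where the respective solve failed).
#' @export
fluxVariability <- function(tree, objective = "objective", fraction = 1,
                            targets = NULL) {
  obj <- .objectiveValueAt(tree, objective)
  s1 <- optimizeTree(tree, obj, "max")
  if (s1@status != "optimal")
    stop(sprintf("stage-1 FBA not optimal (%s)", s1@status))
  t2 <- .withObjectiveFloor(tree, obj, fraction * s1@objectiveValue)
  if (is.null(targets)) targets <- .fluxLeafPaths(tree)
  res <- data.frame(path = targets, min = NA_real_, max = NA_real_,
                    statusMin = "", statusMax = "")
  for (i in seq_along(targets)) {
    leaf <- accessPath(tree, targets[[i]])
    if (is.null(leaf) || !is(leaf, "Constraint")) {
      res$statusMin[i] <- res$statusMax[i] <- "missing"
      next
    }
    lo <- optimizeTree(t2, leaf@value, "min")
    hi <- optimizeTree(t2, leaf@value, "max")
    res$statusMin[i] <- lo@status; res$statusMax[i] <- hi@status
    if (lo@status == "optimal") res$min[i] <- lo@objectiveValue
    if (hi@status == "optimal") res$max[i] <- hi@objectiveValue
  }
  res
}

#' Production envelope
#'
#' Sweeps one or two tracked quantities over fixed grids: at each grid point
#' the dimension leaves are re-bound to `EqualTo(point)` and the objective is
#' both maximized and minimized.  Infeasible points are marked rather than
#' fatal.
#'
#' @param tree a [ConstraintTree-class].
#' @param objective path of the tracked objective leaf.
#' @param dims character vector of 1 or 2 leaf paths to fix.
#' @param grids list of numeric grids, parallel to `dims`.
#' @return data.frame with one column per dimension (named by its path),
#'   plus `objectiveMin`, `objectiveMax`, `feasible`.
#' @export
productionEnvelope <- function(tree, objective = "objective", dims, grids) {
  stopifnot(length(dims) %in% c(1L, 2L), length(grids) == length(dims))
  obj <- .objectiveValueAt(tree, objective)
  pts <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(pts) <- dims
  res <- pts
  res$objectiveMin <- NA_real_
  res$objectiveMax <- NA_real_
  res$feasible <- FALSE
  for (k in seq_len(nrow(pts))) {
    t2 <- tree
    for (d in seq_along(dims)) {
      leaf <- accessPath(tree, dims[[d]])
      if (is.null(leaf)) stop(sprintf("dimension path '%s' not found", dims[[d]]))
      t2 <- replaceAt(t2, dims[[d]],
                      constraint(leaf@value, equalTo(pts[k, d])))
    }
    hi <- optimizeTree(t2, obj, "max")
    lo <- optimizeTree(t2, obj, "min")
    if (hi@status == "optimal" && lo@status == "optimal") {
      res$objectiveMax[k] <- hi@objectiveValue
      res$objectiveMin[k] <- lo@objectiveValue
      res$feasible[k] <- TRUE
    }
  }
  res
}

#' Maximal feasible growth rate by bisection
#'
#' For constraint systems that are linear only at a fixed growth rate (sRBA,
#' community balanced growth), feasibility is monotone non-increasing in
#' `mu`; the largest feasible `mu` is found by bisecting the bracket
#' `[lo, hi]`.  The returned value is the largest *verified feasible* lower
#' bracket end, so the reported growth rate always admits a solution.
#'
#' @param builder function `mu -> ConstraintTree` (a feasibility system).
#' @param lo,hi initial bracket; `builder(lo)` must be feasible.
#' @param tol bracket width at which to stop (default 1e-4).
#' @param maxIter iteration cap (default 64).
#' @return `mu*`, the largest verified feasible growth rate.
#' @export
growthBisection <- function(builder, lo = 0, hi, tol = 1e-4, maxIter = 64L) {
  ## a "failed" solve can only arise on the knife edge of feasibility; it is
  ## classified as infeasible so the result stays a verified-feasible point
  feas <- function(mu) optimizeTree(builder(mu), constantValue(0), "min")@status == "optimal"
  if (!feas(lo))
    stop(sprintf("builder(%g) is infeasible: no bracket", lo))
  if (feas(hi)) return(hi)
  it <- 0L
  while (hi - lo > tol) {
    if (it >= maxIter)
      stop(sprintf("bisection did not converge: bracket [%g, %g]", lo, hi))
    mid <- (lo + hi) / 2
    if (feas(mid)) lo <- mid else hi <- mid
    it <- it + 1L
  }
  lo
}

## simplex lattice ------------------------------------------------------------

#' Exact simplex lattice grid
#'
#' All compositions of `k` into `m` non-negative integer parts, as abundance
#' vectors `parts / k`; there are `choose(k + m - 1, m - 1)` of them.  Exact
#' rational lattice points avoid floating drift across screens.
#'
#' @param m number of members (>= 1).
#' @param k grid resolution (denominator, >= 1).
#' @return matrix with `m` columns, one row per lattice point.
#' @export
simplexGrid <- function(m, k) {
  stopifnot(m >= 1L, k >= 1L)
  rec <- function(m, k) {
    if (m == 1L) return(matrix(k, 1, 1))
    out <- list()
    for (first in 0:k) {
      rest <- rec(m - 1L, k - first)
      out[[length(out) + 1L]] <- cbind(first, rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(m, k) / k
}

#' Screen community growth over the composition simplex
#'
#' Evaluates the optimal community growth rate at every simplex lattice
#' point with denominator `k`.  With `muSolver = "fba"` (communities whose
#' constraints are linear in the fluxes, i.e. FBA or enzyme-constrained
#' members) each point is one LP maximizing the community growth variable.
#' With `muSolver = "bisection"` the caller supplies `transform(tree, mu)`
#' returning a feasibility system at fixed `mu`, and [growthBisection()]
#' recovers `mu*`.  Points where the solve fails or growth is infeasible are
#' recorded as `mu = 0`.
#'
#' @param spec a [CommunitySpec-class]; its abundances slot is a template
#'   and is replaced at every grid point.
#' @param k simplex grid resolution (>= 1).
#' @param muSolver `"fba"` or `"bisection"`.
#' @param transform for `"bisection"`: function `(tree, mu) -> tree`.
#' @param hi,tol bisection bracket top and tolerance.
#' @return data.frame with one abundance column per member id plus `mu`;
#'   attribute `"argmax"` holds the row index of the best grid point.
#' @export
compositionScreen <- function(spec, k, muSolver = c("fba", "bisection"),
                              transform = NULL, hi = 10, tol = 1e-4) {
  muSolver <- match.arg(muSolver)
  stopifnot(is(spec, "CommunitySpec"), k >= 1L)
  ids <- vapply(spec@members, function(m) m$id, character(1))
  if (length(ids) < 2L) stop("composition screens need at least 2 members")
  grid <- simplexGrid(length(ids), as.integer(k))
  colnames(grid) <- ids
  mu <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ab <- stats::setNames(grid[i, ], ids)
    sp <- initialize(spec, abundances = ab)
    mu[i] <- tryCatch({
      tree <- communityConstraints(sp)
      if (muSolver == "fba") {
        r <- fluxBalanceAnalysis(tree)
        if (r$status == "optimal") max(r$objective, 0) else 0
      } else {
        if (is.null(transform)) stop("bisection screening needs a transform")
        growthBisection(function(m) transform(tree, m), lo = 0, hi = hi,
                        tol = tol)
      }
    }, error = function(e) 0)
  }
  res <- data.frame(grid, mu = mu, check.names = FALSE)
  attr(res, "argmax") <- which.max(mu)
  res
}
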