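#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

## ---- values and bounds -----------------------------------------------------

#' Sparse linear expression over a global variable space
#'
#' A `LinearValue` is a constant plus a sparse linear combination of
#' variables identified by positive integer indices.  It is the "value" bound
#' by every constraint in a tree.  Indices are 1-based and global within one
#' tree; the constant term lives in its own slot, never at index 0.
#'
#' @slot constant numeric scalar offset (model units).
#' @slot idx strictly increasing integer vector of variable indices (>= 1).
#' @slot coef numeric coefficients parallel to `idx`; zeros are never stored.
#' @seealso [linearValue()], [substituteValue()]
#' @export
setClass("LinearValue",
  slots = c(constant = "numeric", idx = "integer", coef = "numeric"),
  prototype = prototype(constant = 0, idx = integer(0), coef = numeric(0)))

setValidity("LinearValue", function(object) {
  msg <- character(0)
  if (length(object@constant) != 1L || !is.finite(object@constant))
    msg <- c(msg, "constant must be a single finite number")
  if (length(object@idx) != length(object@coef))
    msg <- c(msg, "idx and coef must have equal length")
  if (length(object@idx)) {
    if (any(object@idx < 1L)) msg <- c(msg, "variable indices must be >= 1")
    if (is.unsorted(object@idx, strictly = TRUE))
      msg <- c(msg, "variable indices must be strictly increasing")
    if (any(object@coef == 0)) msg <- c(msg, "zero coefficients must not be stored")
    if (any(!is.finite(object@coef))) msg <- c(msg, "coefficients must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Bounds attachable to a constraint value
#'
#' A `Bound` is one of three kinds: `EqualToBound` (the value must equal a
#' number), `BetweenBound` (the value must lie in a possibly half-infinite
#' interval), or `AbsentBound` (the value is tracked but not constrained,
#' e.g. an objective).
#'
#' @aliases EqualToBound-class BetweenBound-class AbsentBound-class
#' @seealso [equalTo()], [between()], [absentBound()]
#' @export
setClass("Bound", representation("VIRTUAL"))

#' @export
setClass("EqualToBound", contains = "Bound", slots = c(value = "numeric"))

#' @export
setClass("BetweenBound", contains = "Bound",
  slots = c(lower = "numeric", upper = "numeric"))

#' @export
setClass("AbsentBound", contains = "Bound")

setValidity("EqualToBound", function(object) {
  if (length(object@value) != 1L || is.na(object@value) || !is.finite(object@value))
    "EqualTo bound requires a single finite value" else TRUE
})

setValidity("BetweenBound", function(object) {
  if (length(object@lower) != 1L || length(object@upper) != 1L ||
      is.na(object@lower) || is.na(object@upper))
    return("Between bound requires scalar lower and upper")
  if (object@lower > object@upper)
    return(sprintf("Between bound requires lower <= upper (got %g > %g)",
                   object@lower, object@upper))
  TRUE
})

#' A constraint: a linear value bound to a bound
#'
#' @slot value the [LinearValue-class] expression.
#' @slot bound a [Bound-class]; `AbsentBound` means tracked-only.
#' @seealso [constraint()]
#' @export
setClass("Constraint", slots = c(value = "LinearValue", bound = "Bound"))

## ---- constraint trees ------------------------------------------------------

#' Directory-like tree of labeled constraints
#'
#' The central container: an ordered, uniquely labeled mapping from
#' identifier labels (charset `[A-Za-z0-9_]`) to either a [Constraint-class]
#' leaf or a nested `ConstraintTree`.  The tree imposes no semantics on its
#' labels; display order is insertion order, while all solver-facing
#' orderings are lexicographic by full path.
#'
#' @slot children named list of `Constraint` or `ConstraintTree` nodes.
#' @seealso [constraintTree()], [makeVariables()], [combineIndependent()]
#' @export
setClass("ConstraintTree", slots = c(children = "list"),
  prototype = prototype(children = structure(list(), names = character(0))))

setValidity("ConstraintTree", function(object) {
  ch <- object@children
  if (length(ch) == 0L) return(TRUE)
  nm <- names(ch)
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    return("all children must be named")
  if (anyDuplicated(nm)) return("labels must be unique within a level")
  bad <- nm[!grepl("^[A-Za-z0-9_]+$", nm)]
  if (length(bad))
    return(sprintf("invalid label(s): %s (allowed charset [A-Za-z0-9_])",
                   paste(bad, collapse = ", ")))
  ok <- vapply(ch, function(x) is(x, "Constraint") || is(x, "ConstraintTree"),
               logical(1))
  if (!all(ok)) return("children must be Constraint or ConstraintTree objects")
  TRUE
})

## ---- solver-facing form ----------------------------------------------------

#' Solver-ready flattened linear program
#'
#' The matrix form of a constraint tree: one row per bounded leaf, rows
#' ordered lexicographically by full path (C locale), with any constant term
#' of a leaf value folded into the row bounds.  Leaves with an absent bound
#' produce no row.
#'
#' @slot nVars number of variables (max index referenced by the tree).
#' @slot paths full leaf paths, one per row, in row order.
#' @slot A sparse row coefficient matrix (`dgCMatrix`, rows x nVars).
#' @slot lower,upper per-row bounds; equalities have lower == upper; an
#'   infinite side is `-Inf`/`Inf` (input magnitudes >= 1e30 are mapped to
#'   infinity).
#' @seealso [flattenTree()], [optimizeTree()]
#' @export
setClass("FlatProblem",
  slots = c(nVars = "integer", paths = "character", A = "dgCMatrix",
            lower = "numeric", upper = "numeric"))

setValidity("FlatProblem", function(object) {
  m <- length(object@paths)
  if (nrow(object@A) != m || length(object@lower) != m || length(object@upper) != m)
    return("rows of A, paths, lower, upper must agree")
  if (ncol(object@A) != object@nVars) return("ncol(A) must equal nVars")
  if (any(object@lower > object@upper)) return("row lower > upper")
  TRUE
})

#' Result of solving a flattened constraint tree
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"failed"` (solver failure, distinct from the previous two).
#' @slot assignment variable values (length nVars) when optimal, else empty.
#' @slot objectiveValue attained objective when optimal, else `NA`.
#' @export
setClass("SolverOutcome",
  slots = c(status = "character", assignment = "numeric",
            objectiveValue = "numeric"),
  prototype = prototype(status = "failed", assignment = numeric(0),
                        objectiveValue = NA_real_))

## ---- models ----------------------------------------------------------------

#' Canonical in-memory metabolic model
#'
#' Format-independent representation of a COBRA-style model: metabolites,
#' reactions with flux bounds (mmol/gDW/h) and objective coefficients, a
#' sparse stoichiometric matrix, and per-reaction gene-protein-reaction
#' (GPR) rules.
#'
#' @slot metabolites data.frame with columns `id`, `compartment`.
#' @slot reactions data.frame with columns `id`, `lower`, `upper`,
#'   `objective`.
#' @slot stoich sparse stoichiometric matrix, metabolites x reactions,
#'   dimnames set to the respective ids.
#' @slot gprs named list (by reaction id) of [GprExpr-class] or `NULL`.
#' @slot genes character vector of gene ids.
#' @slot sanitization data.frame logging identifier sanitization performed
#'   on import (columns `category`, `original`, `sanitized`).
#' @seealso [readCobraJson()], [canonicalModel()]
#' @export
setClass("CanonicalModel",
  slots = c(metabolites = "data.frame", reactions = "data.frame",
            stoich = "dgCMatrix", gprs = "list", genes = "character",
            sanitization = "data.frame"))

setValidity("CanonicalModel", function(object) {
  msg <- character(0)
  mets <- object@metabolites; rxns <- object@reactions
  if (!all(c("id", "compartment") %in% names(mets)))
    msg <- c(msg, "metabolites need columns id, compartment")
  if (!all(c("id", "lower", "upper", "objective") %in% names(rxns)))
    msg <- c(msg, "reactions need columns id, lower, upper, objective")
  if (anyDuplicated(mets$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) msg <- c(msg, "duplicate reaction ids")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  if (length(msg)) return(msg)
  if (nrow(rxns) && any(rxns$lower > rxns$upper))
    msg <- c(msg, "reaction lower bound exceeds upper bound")
  if (!identical(dim(object@stoich), c(nrow(mets), nrow(rxns))))
    msg <- c(msg, "stoich dimensions must be metabolites x reactions")
  else {
    rn <- rownames(object@stoich) %||% character(0)
    cn <- colnames(object@stoich) %||% character(0)
    if ((nrow(mets) > 0L && !identical(rn, as.character(mets$id))) ||
        (nrow(rxns) > 0L && !identical(cn, as.character(rxns$id))))
      msg <- c(msg, "stoich dimnames must match metabolite/reaction ids")
  }
  if (length(object@gprs) && !all(names(object@gprs) %in% rxns$id))
    msg <- c(msg, "gprs must be named by declared reaction ids")
  if (length(msg)) msg else TRUE
})

## ---- GPR expressions -------------------------------------------------------

#' Gene-protein-reaction boolean expression
#'
#' Boolean tree over gene ids: `GprLeaf` (one gene), `GprAnd` (all children
#' required, i.e. an enzyme complex), `GprOr` (any child suffices, i.e.
#' isozymes).
#'
#' @aliases GprLeaf-class GprAnd-class GprOr-class
#' @seealso [parseGpr()], [evalGpr()], [gprToIsozymes()]
#' @export
setClass("GprExpr", representation("VIRTUAL"))

#' @export
setClass("GprLeaf", contains = "GprExpr", slots = c(gene = "character"))

#' @export
setClass("GprAnd", contains = "GprExpr", slots = c(children = "list"))

#' @export
setClass("GprOr", contains = "GprExpr", slots = c(children = "list"))

setValidity("GprLeaf", function(object)
  if (length(object@gene) != 1L || !nzchar(object@gene))
    "GprLeaf requires one non-empty gene id" else TRUE)

.validGprChildren <- function(object) {
  if (!length(object@children)) return("children must be non-empty")
  ok <- vapply(object@children, is, logical(1), class2 = "GprExpr")
  if (!all(ok)) "children must be GprExpr objects" else TRUE
}
setValidity("GprAnd", .validGprChildren)
setValidity("GprOr", .validGprChildren)

## ---- kinetics --------------------------------------------------------------

#' One isozyme: a gene set with subunit stoichiometry and turnover numbers
#'
#' @slot geneStoichiometry named numeric of positive subunit counts.
#' @slot kcatFwd,kcatRev turnover numbers (1/h) for the forward/reverse
#'   direction; `NA` when the direction is not catalyzed.
#' @seealso [isozyme()], [KineticsTable-class]
#' @export
setClass("Isozyme",
  slots = c(geneStoichiometry = "numeric", kcatFwd = "numeric",
            kcatRev = "numeric"))

setValidity("Isozyme", function(object) {
  gs <- object@geneStoichiometry
  if (!length(gs) || is.null(names(gs)) || any(!nzchar(names(gs))))
    return("geneStoichiometry must be a named non-empty vector")
  if (any(gs <= 0) || any(gs != round(gs)))
    return("subunit counts must be positive integers")
  for (k in c(object@kcatFwd, object@kcatRev))
    if (!is.na(k) && k <= 0) return("present kcats must be positive")
  TRUE
})

#' Enzyme kinetics and proteome capacity data
#'
#' @slot isozymes named list (by reaction id) of lists of [Isozyme-class].
#' @slot masses named numeric, gene id -> molar mass (g/mmol).
#' @slot lengths named integer, gene id -> protein length (amino acids).
#' @slot capacities named list of capacity groups; each element is
#'   `list(genes = <character vector or "all">, limit = <g/gDW>)`.
#' @seealso [kineticsTable()], [readKineticsTsv()], [enzymeConstraints()]
#' @export
setClass("KineticsTable",
  slots = c(isozymes = "list", masses = "numeric", lengths = "integer",
            capacities = "list"))

setValidity("KineticsTable", function(object) {
  msg <- character(0)
  if (length(object@isozymes) && is.null(names(object@isozymes)))
    msg <- c(msg, "isozymes must be named by reaction id")
  if (length(object@masses) && (is.null(names(object@masses)) ||
      any(object@masses <= 0)))
    msg <- c(msg, "masses must be named and positive")
  if (length(object@lengths) && (is.null(names(object@lengths)) ||
      any(object@lengths <= 0)))
    msg <- c(msg, "lengths must be named positive integers")
  for (g in object@capacities) {
    if (!is.list(g) || !all(c("genes", "limit") %in% names(g)) ||
        g$limit <= 0) {
      msg <- c(msg, "capacity groups need a gene set (or \"all\") and a positive limit")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

## ---- sRBA and communities --------------------------------------------------

#' Parameters of the simplified resource balance layer
#'
#' @slot kt ribosome translation rate (amino acids/ribosome/h).
#' @slot mwR ribosome molar mass (g/mmol).
#' @slot LR ribosome protein length (amino acids).
#' @slot cAtp polymerization ATP cost (mmol ATP per mmol amino acid).
#' @slot Ptotal total proteome capacity (g/gDW).
#' @slot atpHydrolysis named numeric mapping metabolite ids to the
#'   stoichiometry of one ATP hydrolysis event (e.g. ATP -1, ADP +1, Pi +1);
#'   empty to skip the ATP-cost amendment.
#' @seealso [srbaParams()], [srbaConstraints()]
#' @export
setClass("SrbaParams",
  slots = c(kt = "numeric", mwR = "numeric", LR = "numeric", cAtp = "numeric",
            Ptotal = "numeric", atpHydrolysis = "numeric"))

setValidity("SrbaParams", function(object) {
  for (nm in c("kt", "mwR", "LR", "cAtp", "Ptotal")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single positive number", nm))
  }
  if (length(object@atpHydrolysis) && is.null(names(object@atpHydrolysis)))
    return("atpHydrolysis must be named by metabolite id")
  TRUE
})

#' Specification of an abundance-weighted microbial community
#'
#' Each member contributes a pre-built constraint tree (typically from
#' [fluxBalanceConstraints()], possibly with enzyme constraints layered on),
#' the paths of its exchange flux leaves, and the path of its growth
#' objective.  Abundances are dry-weight fractions summing to one.
#'
#' @slot members list of `list(id=, tree=, exchanges=, growth=)` where
#'   `exchanges` is a named character vector (exchange id -> path inside the
#'   member tree) and `growth` is the member's objective path.
#' @slot abundances named numeric (by member id), non-negative, summing to 1.
#' @slot environment named list of [Bound-class] per exchange id, applied to
#'   the community-level exchange variables.
#' @seealso [communitySpec()], [communityConstraints()]
#' @export
setClass("CommunitySpec",
  slots = c(members = "list", abundances = "numeric", environment = "list"))

setValidity("CommunitySpec", function(object) {
  ids <- vapply(object@members, function(m) m$id, character(1))
  if (anyDuplicated(ids)) return("duplicate member ids")
  ab <- object@abundances
  if (!setequal(names(ab), ids)) return("abundances must be named by member ids")
  if (any(ab < 0)) return("abundances must be non-negative")
  if (abs(sum(ab) - 1) > 1e-9)
    return(sprintf("abundances must sum to 1 (got %.12g)", sum(ab)))
  for (m in object@members) {
    if (!all(c("id", "tree", "exchanges", "growth") %in% names(m)))
      return("members need id, tree, exchanges, growth")
    if (!is(m$tree, "ConstraintTree")) return("member tree must be a ConstraintTree")
  }
  if (length(object@environment) && is.null(names(object@environment)))
    return("environment bounds must be named by exchange id")
  TRUE
})

## ---- fixtures --------------------------------------------------------------

#' A synthetic model bundle with a known optimum
#'
#' @slot model the [CanonicalModel-class].
#' @slot kinetics a [KineticsTable-class] or `NULL`.
#' @slot srba a [SrbaParams-class] or `NULL`.
#' @slot analyticOptimum the hand-derived FBA optimum (`NA` if not fixed).
#' @slot description one-line human description.
#' @seealso [toyChainModel()], [toyDiamondModel()], [toyTradeoffModel()]
#' @export
setClass("FixtureBundle",
  slots = c(model = "CanonicalModel", kinetics = "ANY", srba = "ANY",
            analyticOptimum = "numeric", description = "character"))
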