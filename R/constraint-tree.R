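## bound constructors ---------------------------------------------------------

#' Bound constructors
#'
#' @param value,lower,upper bound data; `lower`/`upper` may be `-Inf`/`Inf`.
#' @return a [Bound-class] object of the respective kind.
#' @examples
#' between(0, 10)
#' equalTo(0)
#' absentBound()   # tracked, not constrained
#' @export
equalTo <- function(value) new("EqualToBound", value = as.numeric(value))

#' @rdname equalTo
#' @export
between <- function(lower = -Inf, upper = Inf)
  new("BetweenBound", lower = as.numeric(lower), upper = as.numeric(upper))

#' @rdname equalTo
#' @export
absentBound <- function() new("AbsentBound")

#' Build a constraint from a value and a bound
#'
#' @param value a [LinearValue-class].
#' @param bound a [Bound-class]; defaults to absent (tracked-only).
#' @return a [Constraint-class].
#' @export
constraint <- function(value, bound = absentBound())
  new("Constraint", value = value, bound = bound)

#' Accessors for constraint slots
#' @param x a [Constraint-class].
#' @return `value()` the [LinearValue-class]; `bound()` the [Bound-class].
#' @export
setGeneric("value", function(x) standardGeneric("value"))

#' @rdname value
#' @export
setMethod("value", "Constraint", function(x) x@value)

#' @rdname value
#' @export
setGeneric("bound", function(x) standardGeneric("bound"))

#' @rdname value
#' @export
setMethod("bound", "Constraint", function(x) x@bound)

## path helpers ---------------------------------------------------------------

.splitPath <- function(path) {
  if (length(path) != 1L || is.na(path)) stop("path must be a single string")
  if (path == "") return(character(0))
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (any(!nzchar(parts))) stop(sprintf("malformed path '%s'", path))
  parts
}

.checkLabel <- function(label) {
  if (length(label) != 1L || !grepl("^[A-Za-z0-9_]+$", label))
    stop(sprintf("invalid label '%s' (allowed charset [A-Za-z0-9_])",
                 paste(label, collapse = "/")))
  label
}

## tree construction ----------------------------------------------------------

#' Construct a constraint tree
#'
#' @param children named list of [Constraint-class] or
#'   [ConstraintTree-class] nodes (possibly empty).
#' @return a [ConstraintTree-class].
#' @export
constraintTree <- function(children = list()) {
  if (length(children) == 0L)
    children <- structure(list(), names = character(0))
  new("ConstraintTree", children = children)
}

.insertAt <- function(tree, parts, node) {
  if (length(parts) == 0L) return(node)
  lab <- parts[[1]]
  ch <- tree@children
  if (lab %in% names(ch)) {
    sub <- ch[[lab]]
    if (!is(sub, "ConstraintTree"))
      stop(sprintf("path collision: '%s' is already a leaf", lab))
    ch[[lab]] <- .insertAt(sub, parts[-1], node)
  } else {
    ch[[lab]] <- .insertAt(constraintTree(), parts[-1], node)
  }
  initialize(tree, children = ch)
}

#' Allocate fresh variables as a constraint tree
#'
#' Creates one variable per path, in input order, each held by a leaf whose
#' value is `1 * x_i` and whose bound is the given one.  This is the entry
#' point of every model build: variables exist only through the leaves that
#' carry them.
#'
#' @param paths character vector of distinct `/`-separated paths.
#' @param bounds a single [Bound-class] recycled to all paths, or a list of
#'   bounds parallel to `paths`.
#' @return a [ConstraintTree-class] with `variableCount()` equal to
#'   `length(paths)`.
#' @examples
#' makeVariables(c("fluxes/r1", "fluxes/r2"), between(0, 10))
#' @export
makeVariables <- function(paths, bounds = absentBound()) {
  paths <- as.character(paths)
  if (anyDuplicated(paths))
    stop(sprintf("duplicate path(s): %s",
                 paste(unique(paths[duplicated(paths)]), collapse = ", ")))
  if (is(bounds, "Bound")) bounds <- rep(list(bounds), length(paths))
  if (length(bounds) != length(paths))
    stop("bounds must be a single Bound or one per path")
  tree <- constraintTree()
  for (i in seq_along(paths)) {
    parts <- .splitPath(paths[[i]])
    if (!length(parts)) stop("variable paths must be non-empty")
    for (p in parts) .checkLabel(p)
    tree <- .insertAt(tree, parts,
                      constraint(variableValue(i), bounds[[i]]))
  }
  tree
}

#' Wrap a tree under a single label
#'
#' @param label identifier to prepend.
#' @param tree a [ConstraintTree-class].
#' @return a tree whose single top entry `label` holds `tree`; variables are
#'   untouched.
#' @export
prefixLabel <- function(label, tree) {
  .checkLabel(label)
  stopifnot(is(tree, "ConstraintTree"))
  constraintTree(structure(list(tree), names = label))
}

## counting and renumbering ---------------------------------------------------

#' Number of variables referenced by a tree
#'
#' Returns the maximum variable index referenced anywhere in the object (0
#' for an empty tree).  This is the basis of index renumbering in
#' [combineIndependent()].
#'
#' @param x a [ConstraintTree-class], [Constraint-class] or
#'   [LinearValue-class].
#' @return non-negative integer.
#' @export
setGeneric("variableCount", function(x) standardGeneric("variableCount"))

#' @rdname variableCount
#' @export
setMethod("variableCount", "LinearValue", function(x)
  if (length(x@idx)) max(x@idx) else 0L)

#' @rdname variableCount
#' @export
setMethod("variableCount", "Constraint", function(x) variableCount(x@value))

#' @rdname variableCount
#' @export
setMethod("variableCount", "ConstraintTree", function(x) {
  if (!length(x@children)) return(0L)
  max(vapply(x@children, variableCount, integer(1)))
})

.shiftValue <- function(v, by) {
  if (by == 0L || !length(v@idx)) return(v)
  initialize(v, idx = v@idx + as.integer(by))
}

.shiftTree <- function(tree, by) {
  if (by == 0L) return(tree)
  ch <- lapply(tree@children, function(x)
    if (is(x, "ConstraintTree")) .shiftTree(x, by)
    else initialize(x, value = .shiftValue(x@value, by)))
  initialize(tree, children = ch)
}

## combination ----------------------------------------------------------------

#' Overlay two trees sharing one variable space
#'
#' Recursive union of entries without renumbering; both trees must already
#' refer to the same variable space (the caller's contract).  Any two leaves
#' at the same path collide loudly.
#'
#' @param a,b [ConstraintTree-class] objects.
#' @return the union tree.
#' @export
mergeShared <- function(a, b) .mergeAt(a, b, character(0))

.mergeAt <- function(a, b, where) {
  stopifnot(is(a, "ConstraintTree"), is(b, "ConstraintTree"))
  ch <- a@children
  for (lab in names(b@children)) {
    bn <- b@children[[lab]]
    here <- c(where, lab)
    if (lab %in% names(ch)) {
      an <- ch[[lab]]
      if (is(an, "ConstraintTree") && is(bn, "ConstraintTree"))
        ch[[lab]] <- .mergeAt(an, bn, here)
      else
        stop(sprintf("collision at %s", paste(here, collapse = "/")))
    } else ch[[lab]] <- bn
  }
  initialize(a, children = ch)
}

#' Concatenate two trees over independent variable spaces
#'
#' Every variable index `i` of `b` becomes `i + variableCount(a)`, then the
#' entries are unioned.  `a` is never altered, and `b`'s constraints are
#' identical up to the index shift, so independently built blocks can be
#' welded together without manual index bookkeeping.
#'
#' @param a,b [ConstraintTree-class] objects with disjoint entries (prefix
#'   them first if needed).
#' @return the combined tree.
#' @examples
#' a <- makeVariables(c("x", "y"), between(0, 1))
#' b <- makeVariables("z", between(0, 2))
#' combineIndependent(a, b)  # z holds x3
#' @export
combineIndependent <- function(a, b) {
  stopifnot(is(a, "ConstraintTree"), is(b, "ConstraintTree"))
  mergeShared(a, .shiftTree(b, variableCount(a)))
}

## traversal ------------------------------------------------------------------

#' Fetch the node at a path
#'
#' @param tree a [ConstraintTree-class].
#' @param path `/`-separated path; `""` addresses the root.
#' @return the [Constraint-class] or [ConstraintTree-class] at `path`, or
#'   `NULL` when the path does not exist.
#' @export
accessPath <- function(tree, path) {
  stopifnot(is(tree, "ConstraintTree"))
  node <- tree
  for (lab in .splitPath(path)) {
    if (!is(node, "ConstraintTree")) return(NULL)
    if (!lab %in% names(node@children)) return(NULL)
    node <- node@children[[lab]]
  }
  node
}

#' @describeIn ConstraintTree-class `tree[["a/b"]]` is [accessPath()].
#' @param x,i tree and path.
#' @export
setMethod("[[", c("ConstraintTree", "character"), function(x, i) accessPath(x, i))

#' @describeIn ConstraintTree-class `tree$label` fetches a direct child.
#' @param name child label.
#' @export
setMethod("$", "ConstraintTree", function(x, name) x@children[[name]])

#' Replace the node at a path
#'
#' Returns a new tree in which the node at `path` is substituted (the
#' remainder is shared).  The parent of `path` must exist; replacing at the
#' root path `""` returns `node` itself.  This is the primitive behind
#' re-binding, e.g. forcing a knocked-out flux to zero.
#'
#' @param tree a [ConstraintTree-class].
#' @param path `/`-separated path.
#' @param node replacement [Constraint-class] or [ConstraintTree-class].
#' @return the updated tree.
#' @export
replaceAt <- function(tree, path, node) {
  stopifnot(is(tree, "ConstraintTree"))
  parts <- .splitPath(path)
  if (!length(parts)) return(node)
  .replaceParts(tree, parts, node, path)
}

.replaceParts <- function(tree, parts, node, full) {
  lab <- parts[[1]]
  ch <- tree@children
  if (length(parts) == 1L) {
    ch[[lab]] <- node
  } else {
    if (!lab %in% names(ch) || !is(ch[[lab]], "ConstraintTree"))
      stop(sprintf("missing parent for path '%s'", full))
    ch[[lab]] <- .replaceParts(ch[[lab]], parts[-1], node, full)
  }
  initialize(tree, children = ch)
}

#' Transform every leaf of a tree
#'
#' @param f function `Constraint -> Constraint`.
#' @param tree a [ConstraintTree-class].
#' @return a shape-identical tree with `f` applied to each leaf; an error in
#'   `f` is re-signalled with the offending path.
#' @export
mapLeaves <- function(f, tree) .mapLeavesAt(f, tree, character(0))

.mapLeavesAt <- function(f, tree, where) {
  ch <- lapply(seq_along(tree@children), function(i) {
    x <- tree@children[[i]]
    here <- c(where, names(tree@children)[[i]])
    if (is(x, "ConstraintTree")) return(.mapLeavesAt(f, x, here))
    out <- tryCatch(f(x), error = function(e)
      stop(sprintf("mapLeaves failed at '%s': %s",
                   paste(here, collapse = "/"), conditionMessage(e)), call. = FALSE))
    if (!is(out, "Constraint")) stop(sprintf(
      "mapLeaves function must return a Constraint (at '%s')",
      paste(here, collapse = "/")), call. = FALSE)
    out
  })
  names(ch) <- names(tree@children)
  initialize(tree, children = ch)
}

#' Leaf paths and leaves of a tree
#'
#' @param tree a [ConstraintTree-class].
#' @return `leafPaths()`: character vector of full `/`-separated leaf paths
#'   in insertion order; `leaves()`: the corresponding named list of
#'   [Constraint-class] objects.
#' @export
leafPaths <- function(tree) names(leaves(tree))

#' @rdname leafPaths
#' @export
leaves <- function(tree) {
  stopifnot(is(tree, "ConstraintTree"))
  out <- list()
  rec <- function(node, prefix) {
    for (lab in names(node@children)) {
      x <- node@children[[lab]]
      p <- if (nzchar(prefix)) paste(prefix, lab, sep = "/") else lab
      if (is(x, "ConstraintTree")) rec(x, p) else out[[p]] <<- x
    }
  }
  rec(tree, "")
  out
}

## solutions ------------------------------------------------------------------

#' Evaluate a tree at a variable assignment
#'
#' Returns the solved model in the same shape as the constraint tree: a
#' nested named list whose leaves are the numeric values of the corresponding
#' constraint values under `assignment`.
#'
#' @param tree a [ConstraintTree-class].
#' @param assignment numeric vector covering `variableCount(tree)`.
#' @return nested named list with numeric leaves.
#' @export
solutionTree <- function(tree, assignment) {
  stopifnot(is(tree, "ConstraintTree"))
  if (variableCount(tree) > length(assignment))
    stop(sprintf("assignment of length %d too short for %d variables",
                 length(assignment), variableCount(tree)))
  rec <- function(node) {
    out <- lapply(node@children, function(x)
      if (is(x, "ConstraintTree")) rec(x)
      else substituteValue(x@value, assignment))
    out
  }
  rec(tree)
}

## display --------------------------------------------------------------------

.formatBound <- function(b) {
  if (is(b, "EqualToBound")) sprintf("= %g", b@value)
  else if (is(b, "BetweenBound")) sprintf("in [%g, %g]", b@lower, b@upper)
  else "(tracked)"
}

setMethod("show", "Constraint", function(object) {
  cat("Constraint:", .formatLv(object@value), .formatBound(object@bound), "\n")
})

setMethod("show", "ConstraintTree", function(object) {
  cat(sprintf("ConstraintTree: %d top-level entr%s, %d variable%s\n",
              length(object@children),
              if (length(object@children) == 1L) "y" else "ies",
              variableCount(object),
              if (variableCount(object) == 1L) "" else "s"))
  rec <- function(node, indent, depth) {
    nm <- names(node@children)
    shown <- if (length(nm) > 12L) nm[1:12] else nm
    for (lab in shown) {
      x <- node@children[[lab]]
      if (is(x, "ConstraintTree")) {
        cat(indent, lab, "/ (", length(x@children), " entries)\n", sep = "")
        if (depth < 2L) rec(x, paste0(indent, "  "), depth + 1L)
      } else {
        cat(indent, lab, ": ", .formatLv(x@value), " ",
            .formatBound(x@bound), "\n", sep = "")
      }
    }
    if (length(nm) > 12L) cat(indent, "... ", length(nm) - 12L, " more\n", sep = "")
  }
  rec(object, "  ", 0L)
})
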