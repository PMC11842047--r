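#' Flatten a constraint tree to solver matrix form
#'
#' Produces one row per bounded leaf, ordered lexicographically by full path
#' (byte order, locale-independent), which makes the flattening — and
#' everything downstream of it — fully deterministic.  A constant `c` in a
#' leaf value is folded into the row bounds (`l <= c + a'x <= u` becomes
#' `l - c <= a'x <= u - c`).  Leaves with an absent bound contribute no row;
#' bound magnitudes at or above `1e30` are treated as infinite.
#'
#' @param tree a [ConstraintTree-class].
#' @return a [FlatProblem-class].
#' @examples
#' flattenTree(makeVariables(c("a", "b"), between(0, 10)))
#' @export
flattenTree <- function(tree) {
  stopifnot(is(tree, "ConstraintTree"))
  lv <- leaves(tree)
  n <- variableCount(tree)
  bounded <- vapply(lv, function(x) !is(x@bound, "AbsentBound"), logical(1))
  lv <- lv[bounded]
  paths <- names(lv)
  if (is.null(paths)) paths <- character(0)
  o <- order(paths, method = "radix")
  lv <- lv[o]; paths <- paths[o]
  m <- length(lv)
  lower <- numeric(m); upper <- numeric(m)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  deinf <- function(x) {
    if (is.na(x)) stop("NA bound")
    if (x >= 1e30) Inf else if (x <= -1e30) -Inf else x
  }
  for (i in seq_len(m)) {
    cns <- lv[[i]]
    b <- cns@bound
    if (is(b, "EqualToBound")) { l <- b@value; u <- b@value }
    else { l <- deinf(b@lower); u <- deinf(b@upper) }
    cst <- cns@value@constant
    lower[i] <- l - cst; upper[i] <- u - cst
    k <- length(cns@value@idx)
    if (k) {
      ii <- c(ii, rep.int(i, k)); jj <- c(jj, cns@value@idx)
      xx <- c(xx, cns@value@coef)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
  new("FlatProblem", nVars = as.integer(n), paths = paths,
      A = methods::as(A, "CsparseMatrix"), lower = lower, upper = upper)
}

setMethod("show", "FlatProblem", function(object) {
  cat(sprintf("FlatProblem: %d rows, %d variables\n",
              length(object@paths), object@nVars))
})

setMethod("show", "SolverOutcome", function(object) {
  if (object@status == "optimal")
    cat(sprintf("SolverOutcome: optimal, objective %.6g (%d variables)\n",
                object@objectiveValue, length(object@assignment)))
  else cat("SolverOutcome:", object@status, "\n")
})

#' Optimize a linear objective over a constraint tree
#'
#' Flattens the tree and passes it to the LP backend.  When optimal, the
#' reported objective equals the objective value substituted at the returned
#' assignment (including any constant term).
#'
#' @param tree a [ConstraintTree-class].
#' @param objective a [LinearValue-class] whose indices all lie within
#'   `variableCount(tree)`.
#' @param sense `"max"` or `"min"`.
#' @return a [SolverOutcome-class]; status `"infeasible"`/`"unbounded"` as
#'   diagnosed, `"failed"` for a solver breakdown (distinct from both).
#' @examples
#' t <- makeVariables("x", between(0, 10))
#' optimizeTree(t, value(t[["x"]]), "max")   # optimal, 10
#' @export
optimizeTree <- function(tree, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(is(objective, "LinearValue"))
  flat <- flattenTree(tree)
  if (variableCount(objective) > flat@nVars)
    stop(sprintf("objective references variable x%d beyond the tree's %d variables",
                 variableCount(objective), flat@nVars))
  cvec <- numeric(flat@nVars)
  cvec[objective@idx] <- objective@coef
  out <- .solveLp(flat, cvec, sense)
  if (out@status == "optimal")
    out@objectiveValue <- substituteValue(objective, out@assignment)
  out
}

#' Dump a flattened problem in CPLEX LP format
#'
#' Debug aid behind the CLI `--dump-lp` flag: writes the rows of a
#' [FlatProblem-class] plus an objective in the CPLEX LP text dialect.
#' Variables are named `x1..xn`; free variables are declared in the `Bounds`
#' section.
#'
#' @param flat a [FlatProblem-class].
#' @param objective dense coefficient vector (length `nVars`) or a
#'   [LinearValue-class].
#' @param sense `"max"` or `"min"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeLpFile <- function(flat, objective, sense = c("max", "min"), file) {
  sense <- match.arg(sense)
  if (is(objective, "LinearValue")) {
    cvec <- numeric(flat@nVars)
    cvec[objective@idx] <- objective@coef
  } else cvec <- objective
  term <- function(coefs, idxs) {
    if (!length(idxs)) return("0 x1")
    paste(sprintf("%+.12g x%d", coefs, idxs), collapse = " ")
  }
  lines <- c(if (sense == "max") "Maximize" else "Minimize",
             paste(" obj:", term(cvec[cvec != 0], which(cvec != 0))),
             "Subject To")
  Ad <- as.matrix(flat@A)
  for (i in seq_along(flat@paths)) {
    nz <- which(Ad[i, ] != 0)
    t <- term(Ad[i, nz], nz)
    nm <- gsub("/", ".", flat@paths[i])
    l <- flat@lower[i]; u <- flat@upper[i]
    if (is.finite(l) && l == u)
      lines <- c(lines, sprintf(" %s: %s = %.12g", nm, t, l))
    else {
      if (is.finite(u)) lines <- c(lines, sprintf(" %s_ub: %s <= %.12g", nm, t, u))
      if (is.finite(l)) lines <- c(lines, sprintf(" %s_lb: %s >= %.12g", nm, t, l))
    }
  }
  lines <- c(lines, "Bounds",
             sprintf(" x%d free", seq_len(flat@nVars)),
             "End")
  writeLines(lines, file)
  invisible(file)
}
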