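#' Brute-force LP oracle by vertex enumeration
#'
#' Independent test oracle for small linear programs: enumerates every basic
#' point (intersection of `n` active hyperplanes drawn from the finite row
#' bounds plus an enclosing box), keeps the feasible ones, and reads the
#' optimum off the best vertex.  Unboundedness is detected by re-solving
#' with a 100x larger box: if the optimum strictly improves, a feasible ray
#' exists.  Deliberately naive and deterministic; it shares no code with the
#' simplex backend.  Intended for problems whose data magnitudes are far
#' below the box (1e7).
#'
#' @param problem a [FlatProblem-class] with `nVars <= 10` and at most 40
#'   rows.
#' @param objective dense coefficient vector or [LinearValue-class].
#' @param sense `"max"` or `"min"`.
#' @param box enclosing box half-width.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`)
#'   and, when optimal, `value` and `vertex`.
#' @export
lpVertexOracle <- function(problem, objective, sense = c("max", "min"),
                           box = 1e7) {
  sense <- match.arg(sense)
  stopifnot(is(problem, "FlatProblem"))
  n <- problem@nVars
  m <- length(problem@paths)
  if (n > 10L || m > 40L)
    stop(sprintf("oracle size cap exceeded (%d vars, %d rows)", n, m))
  if (is(objective, "LinearValue")) {
    cvec <- numeric(n)
    cvec[objective@idx] <- objective@coef
    cconst <- objective@constant
  } else { cvec <- objective; cconst <- 0 }
  if (n == 0L) {
    ok <- all(problem@lower <= 1e-9) && all(problem@upper >= -1e-9)
    return(if (ok) list(status = "optimal", value = cconst, vertex = numeric(0))
           else list(status = "infeasible"))
  }
  solveAt <- function(B) {
    Ad <- as.matrix(problem@A)
    planes <- list()
    for (i in seq_len(m)) {
      if (is.finite(problem@lower[i]))
        planes[[length(planes) + 1L]] <- list(a = Ad[i, ], b = problem@lower[i])
      if (is.finite(problem@upper[i]) &&
          problem@upper[i] != problem@lower[i])
        planes[[length(planes) + 1L]] <- list(a = Ad[i, ], b = problem@upper[i])
    }
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      planes[[length(planes) + 1L]] <- list(a = e, b = -B)
      planes[[length(planes) + 1L]] <- list(a = e, b = B)
    }
    np <- length(planes)
    if (choose(np, n) > 2e5)
      stop(sprintf("oracle enumeration too large: C(%d, %d) candidate bases", np, n))
    combs <- utils::combn(np, n)
    feasTol <- function(b) 1e-7 * (1 + abs(b))
    best <- NULL; bestVal <- NA_real_; onBox <- FALSE; anyFeasible <- FALSE
    for (k in seq_len(ncol(combs))) {
      sel <- combs[, k]
      M <- do.call(rbind, lapply(planes[sel], `[[`, "a"))
      rhs <- vapply(planes[sel], `[[`, numeric(1), "b")
      x <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(x) || any(!is.finite(x))) next
      Ax <- as.vector(Ad %*% x)
      lo <- problem@lower; up <- problem@upper
      if (any(Ax < lo - vapply(lo, feasTol, numeric(1)) |
              Ax > up + vapply(up, feasTol, numeric(1)), na.rm = TRUE)) next
      if (any(abs(x) > B + 1e-6 * B)) next
      anyFeasible <- TRUE
      val <- sum(cvec * x)
      better <- is.null(best) ||
        (sense == "max" && val > bestVal + 1e-12) ||
        (sense == "min" && val < bestVal - 1e-12)
      if (better) {
        best <- x; bestVal <- val
        onBox <- any(abs(abs(x) - B) <= 1e-6 * B)
      }
    }
    list(feasible = anyFeasible, value = bestVal, vertex = best, onBox = onBox)
  }
  r1 <- solveAt(box)
  if (!r1$feasible) return(list(status = "infeasible"))
  if (r1$onBox) {
    r2 <- solveAt(box * 100)
    improved <- if (sense == "max") r2$value > r1$value + 1e-3 * (1 + abs(r1$value))
                else r2$value < r1$value - 1e-3 * (1 + abs(r1$value))
    if (improved) return(list(status = "unbounded"))
  }
  list(status = "optimal", value = r1$value + cconst, vertex = r1$vertex)
}
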