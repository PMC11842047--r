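#' Construct a sparse linear value
#'
#' Builds a [LinearValue-class] from a constant and parallel index/coefficient
#' vectors.  Duplicate indices are summed and zero coefficients dropped, so
#' the stored form is always canonical.
#'
#' @param constant numeric offset (default 0).
#' @param idx integer vector of variable indices (1-based).
#' @param coef numeric coefficients, same length as `idx`.
#' @return a [LinearValue-class].
#' @examples
#' linearValue(1, c(1, 2), c(2, 3))   # 1 + 2*x1 + 3*x2
#' @export
linearValue <- function(constant = 0, idx = integer(0), coef = numeric(0)) {
  idx <- as.integer(idx)
  coef <- as.numeric(coef)
  if (length(idx) != length(coef))
    stop("idx and coef must have equal length")
  if (length(idx)) {
    o <- order(idx)
    idx <- idx[o]; coef <- coef[o]
    if (anyDuplicated(idx)) {
      coef <- as.numeric(tapply(coef, idx, sum))
      idx <- sort(unique(idx))
    }
    keep <- coef != 0
    idx <- idx[keep]; coef <- coef[keep]
  }
  new("LinearValue", constant = as.numeric(constant), idx = idx, coef = coef)
}

#' A single-variable linear value
#'
#' @param i positive variable index.
#' @return the [LinearValue-class] `1 * x_i`.
#' @export
variableValue <- function(i) linearValue(0, as.integer(i), 1)

#' A constant-only linear value
#' @param x numeric constant.
#' @return a term-free [LinearValue-class].
#' @export
constantValue <- function(x) linearValue(constant = x)

.lvAdd <- function(a, b, bsign = 1) {
  linearValue(a@constant + bsign * b@constant,
              c(a@idx, b@idx), c(a@coef, bsign * b@coef))
}

.lvScale <- function(a, s) {
  if (length(s) != 1L || !is.finite(s)) stop("scalar multiplier must be a single finite number")
  linearValue(a@constant * s, a@idx, a@coef * s)
}

#' @describeIn LinearValue-class arithmetic: `+`/`-` between linear values
#'   and numbers, `*`/`/` by a scalar, and unary `-`.  Products of two
#'   non-constant values are rejected (values are linear by construction).
#' @param e1,e2 operands.
#' @export
setMethod("Arith", signature("LinearValue", "LinearValue"), function(e1, e2) {
  switch(.Generic,
    "+" = .lvAdd(e1, e2),
    "-" = .lvAdd(e1, e2, -1),
    "*" = {
      if (length(e1@idx) == 0L) .lvScale(e2, e1@constant)
      else if (length(e2@idx) == 0L) .lvScale(e1, e2@constant)
      else stop("product of two non-constant linear values is not linear")
    },
    stop(sprintf("operation '%s' not defined for linear values", .Generic)))
})

#' @export
setMethod("Arith", signature("LinearValue", "numeric"), function(e1, e2) {
  switch(.Generic,
    "+" = .lvAdd(e1, constantValue(e2)),
    "-" = .lvAdd(e1, constantValue(e2), -1),
    "*" = .lvScale(e1, e2),
    "/" = .lvScale(e1, 1 / e2),
    stop(sprintf("operation '%s' not defined for linear values", .Generic)))
})

#' @export
setMethod("Arith", signature("numeric", "LinearValue"), function(e1, e2) {
  switch(.Generic,
    "+" = .lvAdd(constantValue(e1), e2),
    "-" = .lvAdd(constantValue(e1), e2, -1),
    "*" = .lvScale(e2, e1),
    stop(sprintf("operation '%s' not defined for linear values", .Generic)))
})

#' @export
setMethod("Arith", signature("LinearValue", "missing"), function(e1, e2) {
  switch(.Generic,
    "+" = e1,
    "-" = .lvScale(e1, -1),
    stop(sprintf("unary '%s' not defined for linear values", .Generic)))
})

#' Evaluate a linear value at a variable assignment
#'
#' @param value a [LinearValue-class].
#' @param assignment numeric vector; position `i` is the value of variable
#'   `x_i`.  Must cover every index the value references.
#' @return `constant + sum(coef * assignment[idx])`.
#' @examples
#' substituteValue(linearValue(1, 1:2, c(2, 3)), c(1, 2))  # 9
#' @export
substituteValue <- function(value, assignment) {
  stopifnot(is(value, "LinearValue"))
  if (length(value@idx) && max(value@idx) > length(assignment))
    stop(sprintf("assignment of length %d too short for variable x%d",
                 length(assignment), max(value@idx)))
  value@constant + sum(value@coef * assignment[value@idx])
}

.formatLv <- function(object) {
  if (!length(object@idx)) return(format(object@constant))
  terms <- sprintf("%g*x%d", object@coef, object@idx)
  s <- paste(terms, collapse = " + ")
  if (object@constant != 0) s <- paste(s, "+", format(object@constant))
  gsub("\\+ -", "- ", s)
}

setMethod("show", "LinearValue", function(object) {
  cat("LinearValue:", .formatLv(object), "\n")
})
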