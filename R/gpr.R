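#' Parse a gene-protein-reaction rule
#'
#' Grammar: gene identifiers combined with `and`/`or` (case-insensitive) and
#' parentheses; `and` binds tighter than `or`.  An empty or all-whitespace
#' rule means "no gene requirement" and parses to `NULL`.
#'
#' @param rule character scalar, e.g. `"g1 and (g2 or g3)"`.
#' @return a [GprExpr-class] or `NULL` for an absent rule.
#' @examples
#' parseGpr("a or b and c")   # Or(a, And(b, c))
#' @export
parseGpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!nzchar(trimws(rule))) return(NULL)
  toks <- .gprTokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$rule <- rule
  expr <- .gprParseOr(st)
  if (st$pos <= length(st$toks))
    .gprFail(st, sprintf("unexpected token '%s'", st$toks[[st$pos]]$text))
  expr
}

.gprTokenize <- function(rule) {
  toks <- list()
  i <- 1L; n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L; next
    }
    m <- regmatches(substr(rule, i, n),
                    regexpr("^[^\\s()]+", substr(rule, i, n), perl = TRUE))
    if (!length(m)) stop(sprintf("GPR parse error at position %d: bad character '%s'", i, ch))
    low <- tolower(m)
    type <- if (low == "and") "and" else if (low == "or") "or" else "ident"
    toks[[length(toks) + 1L]] <- list(type = type, text = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

.gprFail <- function(st, what) {
  at <- if (st$pos <= length(st$toks)) st$toks[[st$pos]]$at else nchar(st$rule) + 1L
  stop(sprintf("GPR parse error at position %d: %s", at, what), call. = FALSE)
}

.gprPeek <- function(st)
  if (st$pos <= length(st$toks)) st$toks[[st$pos]]$type else "eof"

.gprParseOr <- function(st) {
  kids <- list(.gprParseAnd(st))
  while (.gprPeek(st) == "or") {
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- .gprParseAnd(st)
  }
  if (length(kids) == 1L) kids[[1]] else new("GprOr", children = kids)
}

.gprParseAnd <- function(st) {
  kids <- list(.gprParseAtom(st))
  while (.gprPeek(st) == "and") {
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- .gprParseAtom(st)
  }
  if (length(kids) == 1L) kids[[1]] else new("GprAnd", children = kids)
}

.gprParseAtom <- function(st) {
  t <- .gprPeek(st)
  if (t == "(") {
    st$pos <- st$pos + 1L
    e <- .gprParseOr(st)
    if (.gprPeek(st) != ")") .gprFail(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(e)
  }
  if (t == "ident") {
    g <- st$toks[[st$pos]]$text
    st$pos <- st$pos + 1L
    return(new("GprLeaf", gene = g))
  }
  .gprFail(st, sprintf("expected gene or '(', got '%s'",
                       if (t == "eof") "end of rule" else st$toks[[st$pos]]$text))
}

#' Render a GPR expression back to rule text
#'
#' Inverse of [parseGpr()] up to whitespace and redundant parentheses.
#'
#' @param expr a [GprExpr-class] or `NULL`.
#' @return character scalar (`""` for `NULL`).
#' @export
printGpr <- function(expr) {
  if (is.null(expr)) return("")
  rec <- function(e, parentOr) {
    if (is(e, "GprLeaf")) return(e@gene)
    if (is(e, "GprAnd"))
      return(paste(vapply(e@children, rec, character(1), parentOr = FALSE),
                   collapse = " and "))
    s <- paste(vapply(e@children, rec, character(1), parentOr = TRUE),
               collapse = " or ")
    if (parentOr) s else sprintf("(%s)", s)
  }
  if (is(expr, "GprOr")) {
    paste(vapply(expr@children, function(k) rec(k, FALSE), character(1)),
          collapse = " or ")
  } else rec(expr, FALSE)
}

#' Evaluate a GPR rule under a gene knockout set
#'
#' @param expr a [GprExpr-class] or `NULL` (no requirement, always `TRUE`).
#' @param knockedOut character vector of knocked-out gene ids.
#' @return `TRUE` when the reaction retains catalysis, else `FALSE`.
#' @examples
#' evalGpr(parseGpr("g1 and (g2 or g3)"), "g2")   # TRUE
#' @export
evalGpr <- function(expr, knockedOut = character(0)) {
  if (is.null(expr)) return(TRUE)
  if (is(expr, "GprLeaf")) return(!(expr@gene %in% knockedOut))
  vals <- vapply(expr@children, evalGpr, logical(1), knockedOut = knockedOut)
  if (is(expr, "GprAnd")) all(vals) else any(vals)
}

#' Expand a GPR rule into isozyme gene sets
#'
#' Converts the boolean rule to disjunctive normal form; each conjunct is one
#' isozyme's gene set.  Duplicate conjuncts and supersets of other conjuncts
#' are removed (absorption), since a superset isozyme is never required when
#' its subset suffices.
#'
#' @param expr a [GprExpr-class] or `NULL`.
#' @param maxConjuncts expansion cap; exceeding it is an error, never a
#'   silent truncation.
#' @return list of character vectors (sorted gene sets); empty list for
#'   `NULL`.
#' @examples
#' gprToIsozymes(parseGpr("g1 and (g2 or g3)"))   # {g1,g2}, {g1,g3}
#' @export
gprToIsozymes <- function(expr, maxConjuncts = 10000L) {
  if (is.null(expr)) return(list())
  rec <- function(e) {
    if (is(e, "GprLeaf")) return(list(e@gene))
    parts <- lapply(e@children, rec)
    if (is(e, "GprOr")) {
      out <- do.call(c, parts)
      if (length(out) > maxConjuncts)
        stop(sprintf("GPR DNF expansion exceeds %d conjuncts", maxConjuncts))
      return(out)
    }
    ## And: cross product of children's conjunct lists
    out <- list(character(0))
    for (p in parts) {
      out <- unlist(lapply(out, function(a)
        lapply(p, function(b) union(a, b))), recursive = FALSE)
      if (length(out) > maxConjuncts)
        stop(sprintf("GPR DNF expansion exceeds %d conjuncts", maxConjuncts))
    }
    out
  }
  sets <- lapply(rec(expr), function(s) sort(unique(s)))
  sets <- unique(sets)
  ## absorption: drop strict supersets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (i == j || !keep[j]) next
      if (all(sets[[j]] %in% sets[[i]]) && length(sets[[j]]) < length(sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

setMethod("show", "GprLeaf", function(object) cat("GPR:", printGpr(object), "\n"))
setMethod("show", "GprAnd", function(object) cat("GPR:", printGpr(object), "\n"))
setMethod("show", "GprOr", function(object) cat("GPR:", printGpr(object), "\n"))
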