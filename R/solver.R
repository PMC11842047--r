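## Dense two-phase primal simplex with Bland's rule.
##
## Small, deterministic LP solver used behind the single narrow interface
## .solveLp(FlatProblem, objective, sense).  Bland's pivoting rule guarantees
## finite termination (no cycling) and full determinism at the cost of speed,
## which is irrelevant at the problem sizes this package targets (tens to a
## few hundreds of variables).

.SIMPLEX_TOL <- 1e-9

## one simplex run on tableau rows Tb (current B^-1 A), rhs >= 0, basis,
## minimizing cost over the columns listed in `allowed`.
.simplexIterate <- function(Tb, rhs, basis, cost, allowed, maxit = 50000L) {
  m <- nrow(Tb)
  allowedMask <- rep(FALSE, ncol(Tb))
  allowedMask[allowed] <- TRUE
  for (it in seq_len(maxit)) {
    cB <- cost[basis]
    red <- cost - as.vector(crossprod(cB, Tb))
    red[basis] <- 0
    cand <- which(allowedMask & red < -.SIMPLEX_TOL)
    if (!length(cand))
      return(list(status = "optimal", Tb = Tb, rhs = rhs, basis = basis,
                  obj = sum(cB * rhs)))
    e <- cand[[1]]                       # Bland: smallest eligible index
    d <- Tb[, e]
    pos <- which(d > .SIMPLEX_TOL)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- rhs[pos] / d[pos]
    best <- min(ratio)
    tied <- pos[ratio <= best + .SIMPLEX_TOL * (1 + abs(best))]
    r <- tied[which.min(basis[tied])]    # Bland tie-break: smallest basis idx
    piv <- Tb[r, e]
    Tb[r, ] <- Tb[r, ] / piv
    rhs[r] <- rhs[r] / piv
    other <- setdiff(seq_len(m), r)
    if (length(other)) {
      fac <- Tb[other, e]
      nz <- which(fac != 0)
      if (length(nz)) {
        o <- other[nz]
        Tb[o, ] <- Tb[o, , drop = FALSE] - outer(fac[nz], Tb[r, ])
        rhs[o] <- rhs[o] - fac[nz] * rhs[r]
      }
    }
    rhs[rhs < 0 & rhs > -.SIMPLEX_TOL] <- 0
    basis[r] <- e
  }
  list(status = "failed")
}

## min cost'x  s.t.  A x {<=,>=,=} b,  x >= 0.
## ctype: character vector over rows in {"le","ge","eq"}.
.simplexSolve <- function(A, b, ctype, cost) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L)
    return(list(status = "optimal", x = rep(0, n)))
  nslack <- sum(ctype != "eq")
  As <- cbind(A, matrix(0, m, nslack))
  j <- n
  for (i in seq_len(m)) {
    if (ctype[i] == "le") { j <- j + 1L; As[i, j] <- 1 }
    else if (ctype[i] == "ge") { j <- j + 1L; As[i, j] <- -1 }
  }
  neg <- b < 0
  if (any(neg)) {
    As[neg, ] <- -As[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ## row equilibration: badly scaled rows otherwise accumulate pivot drift
  rscale <- apply(abs(As), 1, max)
  rscale[rscale == 0] <- 1
  As <- As / rscale
  b <- b / rscale
  ntot <- n + nslack
  ## phase 1: artificial basis
  Tb <- cbind(As, diag(m))
  basis <- ntot + seq_len(m)
  ph1 <- c(rep(0, ntot), rep(1, m))
  r1 <- .simplexIterate(Tb, b, basis, ph1, seq_len(ntot + m))
  if (r1$status != "optimal") return(list(status = "failed"))
  ## rows are equilibrated, so a feasible system leaves only roundoff-level
  ## phase-1 residual; anything above this is a genuine infeasibility
  if (r1$obj > 1e-10 * (1 + max(abs(b), 0))) return(list(status = "infeasible"))
  Tb <- r1$Tb; rhs <- r1$rhs; basis <- r1$basis
  ## drive any basic artificial out, or drop its (redundant) row
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] <= ntot) next
    pcol <- which(abs(Tb[r, seq_len(ntot)]) > 1e-7)
    if (length(pcol)) {
      e <- pcol[[1]]
      piv <- Tb[r, e]
      Tb[r, ] <- Tb[r, ] / piv; rhs[r] <- rhs[r] / piv
      other <- setdiff(seq_len(m), r)
      fac <- Tb[other, e]
      nz <- which(fac != 0)
      if (length(nz)) {
        o <- other[nz]
        Tb[o, ] <- Tb[o, , drop = FALSE] - outer(fac[nz], Tb[r, ])
        rhs[o] <- rhs[o] - fac[nz] * rhs[r]
      }
      basis[r] <- e
    } else keep[r] <- FALSE
  }
  if (!all(keep)) {
    Tb <- Tb[keep, , drop = FALSE]; rhs <- rhs[keep]; basis <- basis[keep]
  }
  ## phase 2: original cost, artificial columns forbidden
  ph2 <- c(cost, rep(0, nslack), rep(0, m))
  r2 <- .simplexIterate(Tb, rhs, basis, ph2, seq_len(ntot))
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- rep(0, ntot + m)
  x[r2$basis] <- r2$rhs
  ## refine: recompute the basic solution from the original (equilibrated)
  ## data, discarding any drift the tableau updates accumulated
  if (all(r2$basis <= ntot)) {
    Ak <- As[keep, r2$basis, drop = FALSE]
    xb <- tryCatch(solve(Ak, b[keep]), error = function(e) NULL)
    if (!is.null(xb) && all(is.finite(xb)) && all(xb > -1e-7)) {
      x <- rep(0, ntot + m)
      x[r2$basis] <- pmax(xb, 0)
    }
  }
  list(status = "optimal", x = x[seq_len(n)], obj = sum(cost * x[seq_len(n)]))
}

## Solve a FlatProblem: variables are free, rows are l <= a'x <= u.
## objective: dense coefficient vector (length nVars); sense "max"/"min".
## Free variables are split x = p - q with p, q >= 0.
.solveLp <- function(flat, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- flat@nVars
  Ad <- as.matrix(flat@A)
  rl <- flat@lower; ru <- flat@upper
  rows <- list(); rhs <- numeric(0); ctype <- character(0)
  for (i in seq_len(length(rl))) {
    a <- if (n) Ad[i, ] else numeric(0)
    if (all(a == 0)) {                       # constant-only row
      if (0 < rl[i] - .SIMPLEX_TOL || 0 > ru[i] + .SIMPLEX_TOL)
        return(new("SolverOutcome", status = "infeasible"))
      next
    }
    if (is.finite(rl[i]) && rl[i] == ru[i]) {
      rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, rl[i]); ctype <- c(ctype, "eq")
    } else {
      if (is.finite(ru[i])) {
        rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, ru[i]); ctype <- c(ctype, "le")
      }
      if (is.finite(rl[i])) {
        rows[[length(rows) + 1L]] <- a; rhs <- c(rhs, rl[i]); ctype <- c(ctype, "ge")
      }
    }
  }
  if (n == 0L) {
    return(new("SolverOutcome", status = "optimal", assignment = numeric(0),
               objectiveValue = 0))
  }
  m <- length(rows)
  A <- if (m) do.call(rbind, rows) else matrix(0, 0, n)
  Asplit <- cbind(A, -A)
  costMin <- c(objective, -objective)
  if (sense == "max") costMin <- -costMin
  res <- .simplexSolve(Asplit, rhs, ctype, costMin)
  if (res$status != "optimal")
    return(new("SolverOutcome", status = res$status))
  x <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  ## row-wise feasibility audit of the returned point
  if (m) {
    Ax <- as.vector(A %*% x)
    tolv <- 1e-9 + 1e-6 * pmax(abs(rhs), 0)
    viol <- (ctype == "eq" & abs(Ax - rhs) > tolv) |
            (ctype == "le" & Ax - rhs > tolv) |
            (ctype == "ge" & rhs - Ax > tolv)
    if (any(viol)) return(new("SolverOutcome", status = "failed"))
  }
  new("SolverOutcome", status = "optimal", assignment = x,
      objectiveValue = sum(objective * x))
}
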