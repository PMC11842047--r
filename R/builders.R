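#' Mass-balance constraint system of a metabolic model
#'
#' The base reconstruction block: one flux variable per reaction (bounded by
#' the model's flux bounds, mmol/gDW/h), one steady-state balance row per
#' metabolite (`sum_r S[m,r] * v_r = 0`), and a tracked objective value
#' (`sum_r c_r * v_r`, unbounded).  Layout:
#'
#' * `fluxes/<reaction>` — flux variables,
#' * `flux_stoichiometry/<metabolite>` — balance rows,
#' * `objective` — tracked objective.
#'
#' @param model a [CanonicalModel-class].
#' @return a [ConstraintTree-class].
#' @export
fluxBalanceConstraints <- function(model) {
  stopifnot(is(model, "CanonicalModel"))
  rx <- model@reactions
  tree <- if (nrow(rx)) {
    makeVariables(paste0("fluxes/", rx$id),
                  lapply(seq_len(nrow(rx)), function(j)
                    between(rx$lower[j], rx$upper[j])))
  } else prefixLabel("fluxes", constraintTree())
  bal <- constraintTree()
  S <- model@stoich
  for (i in seq_len(nrow(model@metabolites))) {
    row <- S[i, ]
    nz <- which(row != 0)
    bal@children[[model@metabolites$id[i]]] <-
      constraint(linearValue(0, nz, row[nz]), equalTo(0))
  }
  tree <- mergeShared(tree, prefixLabel("flux_stoichiometry", bal))
  objv <- linearValue(0, which(rx$objective != 0), rx$objective[rx$objective != 0])
  mergeShared(tree, constraintTree(list(objective = constraint(objv))))
}

#' Apply a gene knockout to a constraint tree
#'
#' Every reaction whose GPR rule evaluates to `FALSE` without the given genes
#' has its flux leaf re-bound to `EqualTo(0)`; reactions without a rule, or
#' whose rule survives, are untouched.  Idempotent and order-independent over
#' gene sets.
#'
#' @param tree a tree containing the `fluxes` subtree built from `model`.
#' @param model the [CanonicalModel-class] the tree was built from.
#' @param genes character vector of knocked-out gene ids; unknown ids warn.
#' @param fluxPrefix path of the flux subtree (default `"fluxes"`).
#' @return the re-constrained tree.
#' @export
knockout <- function(tree, model, genes, fluxPrefix = "fluxes") {
  stopifnot(is(tree, "ConstraintTree"), is(model, "CanonicalModel"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, model@genes)
  if (length(unknown))
    warning(sprintf("unknown gene id(s): %s", paste(unknown, collapse = ", ")))
  if (!length(genes)) return(tree)
  for (rid in names(model@gprs)) {
    if (evalGpr(model@gprs[[rid]], genes)) next
    path <- paste(fluxPrefix, rid, sep = "/")
    leaf <- accessPath(tree, path)
    if (is.null(leaf))
      stop(sprintf("flux leaf '%s' not found in tree", path))
    tree <- replaceAt(tree, path, constraint(leaf@value, equalTo(0)))
  }
  tree
}

#' Layer enzyme-capacity (GECKO-style) constraints onto a flux system
#'
#' For every reaction with kinetics data, directional isozyme fluxes
#' `w[r,i,d] >= 0` are introduced and coupled to the net flux
#' (`v_r = sum_i w_fwd - sum_i w_rev`).  Gene product amounts follow from
#' turnover numbers (`g_p = sum n_{p,i} (w_fwd/kcat_fwd + w_rev/kcat_rev)`,
#' mmol/gDW, tracked), and each capacity group bounds its mass-weighted sum
#' (`sum mw_p g_p <= limit`, g/gDW).  Added subtrees:
#'
#' * `isozyme_fluxes/<reaction>/<isozyme>/{fwd,rev}` — variables,
#' * `directional_coupling/<reaction>` — net-flux link rows,
#' * `gene_product_amounts/<gene>` — tracked enzyme amounts,
#' * `capacity/<group>` — proteome-sector capacity rows.
#'
#' A reaction whose bound is open in a direction for which an isozyme lacks a
#' turnover number is an error, as is any non-positive turnover number.
#' Reactions without kinetics are untouched.
#'
#' @param tree a tree with a `fluxes` subtree built from `model`.
#' @param model the [CanonicalModel-class].
#' @param kinetics a [KineticsTable-class].
#' @param fluxPrefix path of the flux subtree (default `"fluxes"`).
#' @return the extended tree.
#' @export
enzymeConstraints <- function(tree, model, kinetics, fluxPrefix = "fluxes") {
  stopifnot(is(tree, "ConstraintTree"), is(model, "CanonicalModel"),
            is(kinetics, "KineticsTable"))
  rx <- model@reactions
  covered <- names(kinetics@isozymes)
  missing <- setdiff(covered, rx$id)
  if (length(missing))
    stop(sprintf("kinetics for unknown reaction(s): %s",
                 paste(missing, collapse = ", ")))
  ## validate kcats against open directions
  for (rid in covered) {
    j <- match(rid, rx$id)
    fwdOpen <- rx$upper[j] > 0
    revOpen <- rx$lower[j] < 0
    for (iso in kinetics@isozymes[[rid]]) {
      for (k in c(iso@kcatFwd, iso@kcatRev))
        if (!is.na(k) && k <= 0)
          stop(sprintf("non-positive kcat for reaction '%s'", rid))
      if (fwdOpen && is.na(iso@kcatFwd))
        stop(sprintf("reaction '%s' is open forward but an isozyme lacks kcat_fwd", rid))
      if (revOpen && is.na(iso@kcatRev))
        stop(sprintf("reaction '%s' is open in reverse but an isozyme lacks kcat_rev", rid))
    }
  }
  ## fresh isozyme flux variables
  wpaths <- character(0)
  wmeta <- list()   # per path: rid, isoIdx, dir
  for (rid in covered) {
    isos <- kinetics@isozymes[[rid]]
    inames <- names(isos)
    if (is.null(inames)) inames <- rep("", length(isos))
    for (i in seq_along(isos)) {
      ilab <- if (nzchar(inames[i])) inames[i] else sprintf("iso%d", i)
      for (d in c("fwd", "rev")) {
        kc <- if (d == "fwd") isos[[i]]@kcatFwd else isos[[i]]@kcatRev
        if (is.na(kc)) next
        p <- paste("isozyme_fluxes", rid, ilab, d, sep = "/")
        wpaths <- c(wpaths, p)
        wmeta[[p]] <- list(rid = rid, iso = isos[[i]], dir = d, kcat = kc)
      }
    }
  }
  base <- variableCount(tree)
  out <- if (length(wpaths))
    combineIndependent(tree, makeVariables(wpaths, between(0, Inf)))
  else tree
  wvar <- stats::setNames(base + seq_along(wpaths), wpaths)
  ## directional coupling rows
  coupling <- constraintTree()
  for (rid in covered) {
    leaf <- accessPath(out, paste(fluxPrefix, rid, sep = "/"))
    if (is.null(leaf))
      stop(sprintf("flux leaf '%s/%s' not found in tree", fluxPrefix, rid))
    v <- leaf@value
    for (p in wpaths) {
      m <- wmeta[[p]]
      if (m$rid != rid) next
      v <- v + .lvScale(variableValue(wvar[[p]]), if (m$dir == "fwd") -1 else 1)
    }
    coupling@children[[rid]] <- constraint(v, equalTo(0))
  }
  out <- mergeShared(out, prefixLabel("directional_coupling", coupling))
  ## tracked gene product amounts
  gAmt <- list()
  for (p in wpaths) {
    m <- wmeta[[p]]
    for (g in names(m$iso@geneStoichiometry)) {
      contrib <- .lvScale(variableValue(wvar[[p]]),
                          m$iso@geneStoichiometry[[g]] / m$kcat)
      gAmt[[g]] <- if (is.null(gAmt[[g]])) contrib else gAmt[[g]] + contrib
    }
  }
  gtree <- constraintTree()
  for (g in names(gAmt)) gtree@children[[g]] <- constraint(gAmt[[g]])
  out <- mergeShared(out, prefixLabel("gene_product_amounts", gtree))
  ## capacity groups
  ctree <- constraintTree()
  for (gname in names(kinetics@capacities)) {
    grp <- kinetics@capacities[[gname]]
    members <- if (identical(grp$genes, "all")) names(gAmt)
               else intersect(grp$genes, names(gAmt))
    tot <- constantValue(0)
    for (g in members) {
      if (!g %in% names(kinetics@masses))
        stop(sprintf("missing molar mass for gene '%s'", g))
      tot <- tot + .lvScale(gAmt[[g]], kinetics@masses[[g]])
    }
    ctree@children[[gname]] <- constraint(tot, between(-Inf, grp$limit))
  }
  if (length(kinetics@capacities))
    out <- mergeShared(out, prefixLabel("capacity", ctree))
  out
}
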