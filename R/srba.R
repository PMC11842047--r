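#' Parameters for the simplified resource balance layer
#'
#' Defaults are literature-scale values for a fast-growing bacterium:
#' translation rate `kt = 45000` aa/ribosome/h (12.5 aa/s), ribosome molar
#' mass `mwR = 2700` g/mmol, ribosome protein length `LR = 7459` aa,
#' polymerization cost `cAtp = 4.3` mmol ATP per mmol amino acid, total
#' proteome capacity `Ptotal = 0.55` g/gDW.  `atpHydrolysis` maps the
#' model's own metabolite ids to the stoichiometry of one hydrolysis event
#' (e.g. `c(atp_c = -1, adp_c = 1, pi_c = 1)`); the default is empty, which
#' skips the ATP-cost amendment, because metabolite ids are model-specific.
#'
#' @param kt translation rate (aa/ribosome/h).
#' @param mwR ribosome molar mass (g/mmol).
#' @param LR ribosome protein length (aa).
#' @param cAtp polymerization ATP cost (mmol ATP per mmol aa).
#' @param Ptotal total proteome capacity (g/gDW).
#' @param atpHydrolysis named numeric stoichiometry of ATP hydrolysis.
#' @return a [SrbaParams-class].
#' @export
srbaParams <- function(kt = 45000, mwR = 2700, LR = 7459, cAtp = 4.3,
                       Ptotal = 0.55, atpHydrolysis = numeric(0)) {
  new("SrbaParams", kt = kt, mwR = mwR, LR = LR, cAtp = cAtp,
      Ptotal = Ptotal, atpHydrolysis = atpHydrolysis)
}

setMethod("show", "SrbaParams", function(object) {
  cat(sprintf(paste0("SrbaParams: kt=%g aa/h, mwR=%g g/mmol, LR=%d aa, ",
                     "cAtp=%g, Ptotal=%g g/gDW\n"),
              object@kt, object@mwR, as.integer(object@LR), object@cAtp,
              object@Ptotal))
})

#' Layer simplified resource-balance constraints at a fixed growth rate
#'
#' Extends an enzyme-constrained tree with ribosome kinetics, utilization
#' and capacity, protein polymerization ATP costs, and growth dilution of
#' gene products.  All added constraints are linear because the growth rate
#' `mu` is fixed; maximal growth is recovered by an outer search
#' ([growthBisection()]).  Added blocks:
#'
#' * `ribosome` — ribosome concentration variable `R >= 0` (mmol/gDW),
#' * `protein_synthesis/<gene>` — synthesis fluxes `s_p >= 0`
#'   (mmol/gDW/h),
#' * `growth_dilution/<gene>` — `s_p - mu * g_p = 0` (dilution by growth),
#' * `ribosome_capacity` — `sum L_p s_p + LR * mu * R <= kt * R`
#'   (utilization including ribosome self-replication),
#' * `polymerization_cost` — tracked total ATP drain; the matching
#'   `flux_stoichiometry` rows are amended in place with
#'   `stoich * cAtp * (sum L_p s_p + LR * mu * R)`,
#' * `proteome_capacity` — `sum mw_p g_p + mwR * R <= Ptotal`.
#'
#' Finally the growth objective leaf is re-bound to `EqualTo(mu)`, turning
#' the system into a feasibility problem at growth rate `mu`.
#'
#' @param tree a tree that already carries [enzymeConstraints()] (i.e. has
#'   `gene_product_amounts`); anything else is an error.
#' @param model the [CanonicalModel-class].
#' @param kinetics the [KineticsTable-class] (protein lengths required).
#' @param params a [SrbaParams-class].
#' @param mu fixed growth rate (1/h), `>= 0`.
#' @param growthPath path of the growth objective leaf (default
#'   `"objective"`).
#' @return the extended tree (a feasibility system at growth `mu`).
#' @export
srbaConstraints <- function(tree, model, kinetics, params, mu,
                            growthPath = "objective") {
  stopifnot(is(tree, "ConstraintTree"), is(params, "SrbaParams"),
            is(kinetics, "KineticsTable"), mu >= 0)
  gnode <- accessPath(tree, "gene_product_amounts")
  if (is.null(gnode))
    stop("srbaConstraints requires enzymeConstraints to be applied first (no gene_product_amounts subtree)")
  geneIds <- names(gnode@children)
  noLen <- setdiff(geneIds, names(kinetics@lengths))
  if (length(noLen))
    stop(sprintf("missing protein length for gene(s): %s",
                 paste(noLen, collapse = ", ")))
  noMass <- setdiff(geneIds, names(kinetics@masses))
  if (length(noMass))
    stop(sprintf("missing molar mass for gene(s): %s",
                 paste(noMass, collapse = ", ")))
  base <- variableCount(tree)
  block <- makeVariables(c("ribosome", paste0("protein_synthesis/", geneIds)),
                         between(0, Inf))
  out <- combineIndependent(tree, block)
  Rvalue <- variableValue(base + 1L)
  svar <- stats::setNames(base + 1L + seq_along(geneIds), geneIds)
  ## growth dilution of gene products: s_p = mu * g_p
  dil <- constraintTree()
  for (g in geneIds) {
    gval <- gnode@children[[g]]@value
    dil@children[[g]] <- constraint(
      variableValue(svar[[g]]) - .lvScale(gval, mu), equalTo(0))
  }
  out <- mergeShared(out, prefixLabel("growth_dilution", dil))
  ## total polymerization load (aa/gDW/h), incl. ribosome self-dilution
  load <- .lvScale(Rvalue, params@LR * mu)
  for (g in geneIds)
    load <- load + .lvScale(variableValue(svar[[g]]),
                            as.numeric(kinetics@lengths[[g]]))
  ## ribosome capacity: load <= kt * R
  out <- mergeShared(out, constraintTree(list(
    ribosome_capacity = constraint(load - .lvScale(Rvalue, params@kt),
                                   between(-Inf, 0)))))
  ## polymerization ATP cost amends the matching balance rows
  for (met in names(params@atpHydrolysis)) {
    p <- paste0("flux_stoichiometry/", met)
    leaf <- accessPath(out, p)
    if (is.null(leaf))
      stop(sprintf("ATP hydrolysis metabolite '%s' has no balance row", met))
    amended <- leaf@value +
      .lvScale(load, params@atpHydrolysis[[met]] * params@cAtp)
    out <- replaceAt(out, p, constraint(amended, leaf@bound))
  }
  out <- mergeShared(out, constraintTree(list(
    polymerization_cost = constraint(.lvScale(load, params@cAtp)))))
  ## proteome capacity: enzyme mass + ribosome mass <= Ptotal
  prot <- .lvScale(Rvalue, params@mwR)
  for (g in geneIds)
    prot <- prot + .lvScale(gnode@children[[g]]@value, kinetics@masses[[g]])
  out <- mergeShared(out, constraintTree(list(
    proteome_capacity = constraint(prot, between(-Inf, params@Ptotal)))))
  ## fix growth: feasibility problem at mu
  gleaf <- accessPath(out, growthPath)
  if (is.null(gleaf))
    stop(sprintf("growth path '%s' not found", growthPath))
  replaceAt(out, growthPath, constraint(gleaf@value, equalTo(mu)))
}
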