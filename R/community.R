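#' Describe a community member
#'
#' @param id member identifier (tree label charset).
#' @param tree the member's [ConstraintTree-class] (fluxes per gDW of this
#'   member).
#' @param exchanges named character vector: exchange id -> path of the
#'   member's exchange flux leaf inside `tree`.
#' @param growth path of the member's growth objective leaf.
#' @return a member description for [communitySpec()].
#' @export
communityMember <- function(id, tree, exchanges, growth = "objective") {
  .checkLabel(id)
  stopifnot(is(tree, "ConstraintTree"))
  if (length(exchanges) && is.null(names(exchanges)))
    stop("exchanges must be named by exchange id")
  list(id = id, tree = tree, exchanges = exchanges, growth = growth)
}

#' Assemble a community specification
#'
#' @param members list of [communityMember()] descriptions.
#' @param abundances named numeric dry-weight fractions (by member id),
#'   non-negative and summing to 1 within 1e-9.
#' @param environment named list of [Bound-class] per exchange id, applied to
#'   the community-level exchange variables (negative flux = uptake, COBRA
#'   convention); exchanges without an entry are left unconstrained.
#' @return a [CommunitySpec-class].
#' @export
communitySpec <- function(members, abundances, environment = list()) {
  new("CommunitySpec", members = members, abundances = abundances,
      environment = environment)
}

#' Build the constraint tree of an abundance-weighted community
#'
#' Member trees are combined over independent variable spaces under
#' `members/<id>`.  For every exchange id declared by any member, a
#' community-level exchange variable `x_e` (per gDW of total community) is
#' linked to the abundance-weighted member fluxes
#' (`x_e - sum_m a_m v_{m,e} = 0`), with any environment bound applied to
#' `x_e`.  A community growth variable `mu` is tied to every member's growth
#' value (equal-growth balanced exponential growth), and `objective` tracks
#' `mu`.  Layout:
#'
#' * `members/<id>/...` — the member trees (indices shifted),
#' * `community_exchanges/<e>` — community exchange variables (environment
#'   bounds),
#' * `exchange_balances/<e>` — abundance-weighted linking rows,
#' * `growth` — the community growth variable (>= 0),
#' * `equal_growth/<id>` — member growth = mu rows,
#' * `objective` — tracks mu.
#'
#' @param spec a [CommunitySpec-class].
#' @return a [ConstraintTree-class].
#' @export
communityConstraints <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  validObject(spec)
  comb <- constraintTree()
  for (m in spec@members)
    comb <- combineIndependent(comb, prefixLabel(m$id, m$tree))
  comb <- prefixLabel("members", comb)
  ## validate exchange and growth paths against the combined tree
  exch <- character(0)
  for (m in spec@members) {
    for (e in names(m$exchanges)) {
      p <- paste("members", m$id, m$exchanges[[e]], sep = "/")
      if (is.null(accessPath(comb, p)))
        stop(sprintf("member '%s': missing exchange path '%s'",
                     m$id, m$exchanges[[e]]))
    }
    if (is.null(accessPath(comb, paste("members", m$id, m$growth, sep = "/"))))
      stop(sprintf("member '%s': missing growth path '%s'", m$id, m$growth))
    exch <- union(exch, names(m$exchanges))
  }
  ## community exchange variables + growth variable
  xbounds <- lapply(exch, function(e)
    if (e %in% names(spec@environment)) spec@environment[[e]] else absentBound())
  block <- makeVariables(c(paste0("community_exchanges/", exch), "growth"),
                         c(xbounds, list(between(0, Inf))))
  base <- variableCount(comb)
  out <- combineIndependent(comb, block)
  xvar <- stats::setNames(base + seq_along(exch), exch)
  muValue <- variableValue(base + length(exch) + 1L)
  ## abundance-weighted exchange balances
  btree <- constraintTree()
  for (e in exch) {
    v <- variableValue(xvar[[e]])
    for (m in spec@members) {
      if (!e %in% names(m$exchanges)) next
      a <- spec@abundances[[m$id]]
      if (a == 0) next
      leaf <- accessPath(out, paste("members", m$id, m$exchanges[[e]], sep = "/"))
      v <- v - .lvScale(leaf@value, a)
    }
    btree@children[[e]] <- constraint(v, equalTo(0))
  }
  out <- mergeShared(out, prefixLabel("exchange_balances", btree))
  ## equal growth
  gtree <- constraintTree()
  for (m in spec@members) {
    leaf <- accessPath(out, paste("members", m$id, m$growth, sep = "/"))
    gtree@children[[m$id]] <- constraint(leaf@value - muValue, equalTo(0))
  }
  out <- mergeShared(out, prefixLabel("equal_growth", gtree))
  mergeShared(out, constraintTree(list(objective = constraint(muValue))))
}
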