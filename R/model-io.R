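## identifier sanitization ----------------------------------------------------

## tree labels are restricted to [A-Za-z0-9_]; model identifiers are
## sanitized on import: disallowed chars -> "_", numeric suffix on collision.
.sanitizeIds <- function(ids, category, log) {
  out <- gsub("[^A-Za-z0-9_]", "_", ids)
  out[!nzchar(out)] <- "_"
  if (anyDuplicated(out)) {
    seen <- character(0)
    for (i in seq_along(out)) {
      cand <- out[i]; k <- 1L
      while (cand %in% seen) { cand <- sprintf("%s_%d", out[i], k); k <- k + 1L }
      out[i] <- cand; seen <- c(seen, cand)
    }
  }
  changed <- which(out != ids)
  if (length(changed))
    log <- rbind(log, data.frame(category = category, original = ids[changed],
                                 sanitized = out[changed]))
  list(ids = out, log = log)
}

.emptySanitization <- function()
  data.frame(category = character(0), original = character(0),
             sanitized = character(0))

## canonical model ------------------------------------------------------------

#' Build a canonical model from its parts
#'
#' Low-level constructor used by the format readers and the toy fixtures.
#' Reaction stoichiometries are given as named numeric vectors over declared
#' metabolite ids.
#'
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower`, `upper`,
#'   `objective`.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite id -> coefficient).
#' @param gprs named list (by reaction id) of [GprExpr-class] or rule strings;
#'   missing entries mean no gene requirement.
#' @param genes character vector of gene ids.
#' @param sanitization optional sanitization log.
#' @return a [CanonicalModel-class].
#' @export
canonicalModel <- function(metabolites, reactions, stoichiometry = list(),
                           gprs = list(), genes = character(0),
                           sanitization = .emptySanitization()) {
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(stoichiometry)) {
    rid <- names(stoichiometry)[[j]]
    jpos <- match(rid, reactions$id)
    if (is.na(jpos)) stop(sprintf("stoichiometry for undeclared reaction '%s'", rid))
    s <- stoichiometry[[j]]
    mpos <- match(names(s), metabolites$id)
    if (anyNA(mpos))
      stop(sprintf("reaction '%s' cites undeclared metabolite '%s'",
                   rid, names(s)[which(is.na(mpos))[1]]))
    ii <- c(ii, mpos); jj <- c(jj, rep.int(jpos, length(s))); xx <- c(xx, s)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  gl <- lapply(gprs, function(g) if (is.character(g)) parseGpr(g) else g)
  gl <- gl[!vapply(gl, is.null, logical(1))]
  ## warn on GPR leaves citing undeclared genes
  if (length(gl)) {
    cited <- unique(unlist(lapply(gl, .gprGenes)))
    unknown <- setdiff(cited, genes)
    if (length(unknown))
      warning(sprintf("GPR rules cite undeclared gene(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  new("CanonicalModel", metabolites = metabolites, reactions = reactions,
      stoich = methods::as(S, "CsparseMatrix"), gprs = gl,
      genes = as.character(genes), sanitization = sanitization)
}

.gprGenes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (is(expr, "GprLeaf")) return(expr@gene)
  unique(unlist(lapply(expr@children, .gprGenes)))
}

#' Model accessors
#' @param x a [CanonicalModel-class].
#' @return the respective slot content.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname reactions
#' @export
setMethod("reactions", "CanonicalModel", function(x) x@reactions)

#' @rdname reactions
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname reactions
#' @export
setMethod("metabolites", "CanonicalModel", function(x) x@metabolites)

#' @rdname reactions
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname reactions
#' @export
setMethod("genes", "CanonicalModel", function(x) x@genes)

#' @rdname reactions
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname reactions
#' @export
setMethod("stoichiometry", "CanonicalModel", function(x) x@stoich)

setMethod("show", "CanonicalModel", function(object) {
  cat(sprintf("CanonicalModel: %d metabolites, %d reactions, %d genes\n",
              nrow(object@metabolites), nrow(object@reactions),
              length(object@genes)))
})

## COBRA JSON -----------------------------------------------------------------

.jsonNum <- function(x, default = NA_real_) {
  if (is.null(x)) default else as.numeric(x)
}

.deinfBound <- function(x) {
  if (x >= 1e30) Inf else if (x <= -1e30) -Inf else x
}

#' Read a COBRA JSON model
#'
#' Reads the cobrapy-compatible JSON schema (keys `metabolites`, `reactions`,
#' `genes`, `lower_bound`, `upper_bound`, `gene_reaction_rule`,
#' `objective_coefficient`).  Missing objective coefficients default to 0;
#' bound magnitudes at or above 1e30 are mapped to infinity; identifiers are
#' sanitized to the tree label charset with a log kept on the model.
#'
#' @param file path to a JSON file.
#' @return a [CanonicalModel-class].
#' @export
readCobraJson <- function(file) {
  if (!file.exists(file)) stop(sprintf("model file '%s' not found", file))
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions"))
    if (!is.list(doc[[key]]))
      stop(sprintf("$.%s: missing or not an array", key))
  log <- .emptySanitization()
  metsRaw <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("$.metabolites[]: missing id")
    as.character(m$id)
  }, character(1))
  comps <- vapply(doc$metabolites, function(m)
    if (is.null(m$compartment)) "" else as.character(m$compartment), character(1))
  s <- .sanitizeIds(metsRaw, "metabolite", log); mets <- s$ids; log <- s$log
  ridsRaw <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("$.reactions[]: missing id")
    as.character(r$id)
  }, character(1))
  s <- .sanitizeIds(ridsRaw, "reaction", log); rids <- s$ids; log <- s$log
  genesRaw <- vapply(doc$genes %||% list(), function(g)
    as.character(g$id), character(1))
  s <- .sanitizeIds(genesRaw, "gene", log); gids <- s$ids; log <- s$log
  geneMap <- stats::setNames(gids, genesRaw)
  metMap <- stats::setNames(mets, metsRaw)
  stoich <- list(); gprs <- list()
  lb <- ub <- obj <- numeric(length(rids))
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    lb[j] <- .deinfBound(.jsonNum(r$lower_bound, -Inf))
    ub[j] <- .deinfBound(.jsonNum(r$upper_bound, Inf))
    if (lb[j] > ub[j])
      stop(sprintf("$.reactions[%d]: lower_bound > upper_bound", j))
    obj[j] <- .jsonNum(r$objective_coefficient, 0)
    sm <- r$metabolites
    if (length(sm)) {
      unknown <- setdiff(names(sm), names(metMap))
      if (length(unknown))
        stop(sprintf("$.reactions[%d].metabolites: unknown metabolite '%s'",
                     j, unknown[[1]]))
      v <- vapply(sm, as.numeric, numeric(1))
      names(v) <- metMap[names(sm)]
      stoich[[rids[j]]] <- v
    }
    rule <- r$gene_reaction_rule
    if (!is.null(rule) && nzchar(trimws(rule))) {
      e <- parseGpr(rule)
      gprs[[rids[j]]] <- .renameGprGenes(e, geneMap)
    }
  }
  canonicalModel(
    metabolites = data.frame(id = mets, compartment = comps),
    reactions = data.frame(id = rids, lower = lb, upper = ub, objective = obj),
    stoichiometry = stoich, gprs = gprs, genes = unname(gids),
    sanitization = log)
}

.renameGprGenes <- function(expr, map) {
  if (is(expr, "GprLeaf")) {
    if (expr@gene %in% names(map)) expr@gene <- unname(map[[expr@gene]])
    else expr@gene <- gsub("[^A-Za-z0-9_]", "_", expr@gene)
    return(expr)
  }
  expr@children <- lapply(expr@children, .renameGprGenes, map = map)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a canonical model as COBRA JSON
#'
#' Infinite bounds are serialized as +/-1e30 (the conventional "infinity"
#' magnitude), so a write/read round trip reproduces the model.
#'
#' @param model a [CanonicalModel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCobraJson <- function(model, file) {
  enfin <- function(x) {
    x[x == Inf] <- 1e30; x[x == -Inf] <- -1e30; x
  }
  rx <- model@reactions
  rl <- lapply(seq_len(nrow(rx)), function(j) {
    col <- model@stoich[, j]
    nz <- which(col != 0)
    mets <- as.list(col[nz])
    names(mets) <- rownames(model@stoich)[nz]
    list(id = rx$id[j],
         lower_bound = enfin(rx$lower[j]), upper_bound = enfin(rx$upper[j]),
         objective_coefficient = rx$objective[j],
         gene_reaction_rule = printGpr(model@gprs[[rx$id[j]]]),
         metabolites = mets)
  })
  ml <- lapply(seq_len(nrow(model@metabolites)), function(i)
    list(id = model@metabolites$id[i],
         compartment = model@metabolites$compartment[i]))
  gl <- lapply(model@genes, function(g) list(id = g))
  jsonlite::write_json(list(metabolites = ml, reactions = rl, genes = gl),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

## SBML (core FBC) ------------------------------------------------------------

#' Read an SBML level 3 model with the FBC extension
#'
#' Compact reader mapping only the core FBC subset this package consumes:
#' species, reactions with stoichiometry, flux bounds resolved through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters, gene products,
#' gene-product associations, and the first active objective.  Annotation
#' and other SBML packages are ignored.
#'
#' @param file path to an SBML XML file.
#' @return a [CanonicalModel-class].
#' @export
readSbml <- function(file) {
  if (!file.exists(file)) stop(sprintf("model file '%s' not found", file))
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  getAttr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  params <- new.env(parent = emptyenv())
  for (p in xml2::xml_find_all(doc, ".//listOfParameters/parameter")) {
    id <- getAttr(p, "id")
    if (!is.null(id)) assign(id, as.numeric(getAttr(p, "value") %||% NA), params)
  }
  resolveBound <- function(pid, default) {
    if (is.null(pid)) return(default)
    if (exists(pid, params)) .deinfBound(get(pid, params)) else default
  }
  log <- .emptySanitization()
  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  metsRaw <- vapply(spn, function(s) getAttr(s, "id") %||% stop("species without id"),
                    character(1))
  comps <- vapply(spn, function(s) getAttr(s, "compartment") %||% "", character(1))
  boundary <- vapply(spn, function(s)
    identical(getAttr(s, "boundaryCondition"), "true"), logical(1))
  s <- .sanitizeIds(metsRaw, "metabolite", log); mets <- s$ids; log <- s$log
  metMap <- stats::setNames(mets, metsRaw)
  gpn <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  genesRaw <- vapply(gpn, function(g) getAttr(g, "id") %||% "", character(1))
  s <- .sanitizeIds(genesRaw, "gene", log); gids <- s$ids; log <- s$log
  geneMap <- stats::setNames(gids, genesRaw)
  ## objective
  objCoef <- new.env(parent = emptyenv())
  objList <- xml2::xml_find_all(doc, ".//*[local-name()='objective']")
  if (length(objList)) {
    for (fo in xml2::xml_find_all(objList[[1]],
                                  ".//*[local-name()='fluxObjective']")) {
      rid <- getAttr(fo, "reaction")
      if (!is.null(rid))
        assign(rid, as.numeric(getAttr(fo, "coefficient") %||% 1), objCoef)
    }
  }
  rn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ridsRaw <- vapply(rn, function(r) getAttr(r, "id") %||% stop("reaction without id"),
                    character(1))
  s <- .sanitizeIds(ridsRaw, "reaction", log); rids <- s$ids; log <- s$log
  stoich <- list(); gprs <- list()
  lb <- ub <- obj <- numeric(length(rids))
  parseAssoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      g <- getAttr(node, "geneProduct")
      return(new("GprLeaf", gene = unname(geneMap[g]) %||% g))
    }
    kids <- lapply(xml2::xml_children(node), parseAssoc)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (!length(kids)) return(NULL)
    if (nm == "and") new("GprAnd", children = kids)
    else if (nm == "or") new("GprOr", children = kids)
    else if (length(kids) == 1L) kids[[1]]
    else NULL
  }
  for (j in seq_along(rn)) {
    r <- rn[[j]]
    rev <- identical(getAttr(r, "reversible"), "true")
    lb[j] <- resolveBound(getAttr(r, "lowerFluxBound"), if (rev) -Inf else 0)
    ub[j] <- resolveBound(getAttr(r, "upperFluxBound"), Inf)
    obj[j] <- if (exists(ridsRaw[j], objCoef)) get(ridsRaw[j], objCoef) else 0
    v <- numeric(0)
    for (sr in xml2::xml_find_all(r, "./listOfReactants/speciesRef|./listOfReactants/speciesReference")) {
      sp <- getAttr(sr, "species")
      if (isTRUE(boundary[match(sp, metsRaw)])) next
      v[metMap[[sp]]] <- -(as.numeric(getAttr(sr, "stoichiometry") %||% 1))
    }
    for (sr in xml2::xml_find_all(r, "./listOfProducts/speciesRef|./listOfProducts/speciesReference")) {
      sp <- getAttr(sr, "species")
      if (isTRUE(boundary[match(sp, metsRaw)])) next
      v[metMap[[sp]]] <- as.numeric(getAttr(sr, "stoichiometry") %||% 1)
    }
    if (length(v)) stoich[[rids[j]]] <- v
    ga <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) {
        e <- parseAssoc(kids[[1]])
        if (!is.null(e)) gprs[[rids[j]]] <- e
      }
    }
  }
  keepMet <- !boundary
  canonicalModel(
    metabolites = data.frame(id = mets[keepMet], compartment = comps[keepMet]),
    reactions = data.frame(id = rids, lower = lb, upper = ub, objective = obj),
    stoichiometry = stoich, gprs = gprs, genes = unname(gids),
    sanitization = log)
}

## solution JSON --------------------------------------------------------------

#' Write a solved value tree as nested JSON
#'
#' Serializes the nested named list returned by [solutionTree()] (or any
#' nested list with numeric leaves) as a JSON object mirroring the tree
#' paths, with reals at 12 significant digits.
#'
#' @param valueTree nested named list with numeric leaves.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSolutionJson <- function(valueTree, file) {
  chk <- function(x) {
    if (is.list(x)) lapply(x, chk)
    else if (!is.numeric(x)) stop("value tree leaves must be numeric")
    invisible(NULL)
  }
  chk(valueTree)
  if (is.list(valueTree) && length(valueTree) == 0L)
    valueTree <- structure(list(), names = character(0))
  jsonlite::write_json(valueTree, file, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE)
  invisible(file)
}

#' Read a solution JSON back into a nested list
#' @param file path written by [writeSolutionJson()].
#' @return nested named list with numeric leaves.
#' @export
readSolutionJson <- function(file)
  jsonlite::fromJSON(file, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
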