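#' Construct an isozyme
#'
#' @param geneStoichiometry named numeric/integer vector of subunit counts
#'   (gene id -> copies per enzyme complex).
#' @param kcatFwd,kcatRev turnover numbers (1/h); `NA` when the direction is
#'   not catalyzed by this isozyme.
#' @return an [Isozyme-class].
#' @export
isozyme <- function(geneStoichiometry, kcatFwd = NA_real_, kcatRev = NA_real_) {
  new("Isozyme", geneStoichiometry = geneStoichiometry,
      kcatFwd = as.numeric(kcatFwd), kcatRev = as.numeric(kcatRev))
}

#' Assemble a kinetics table in code
#'
#' @param isozymes named list (reaction id -> list of [Isozyme-class]).
#' @param masses named numeric, gene id -> molar mass (g/mmol).
#' @param lengths named numeric/integer, gene id -> protein length (aa).
#' @param capacities named list of capacity groups
#'   `list(genes = <ids or "all">, limit = <g/gDW>)`.
#' @return a [KineticsTable-class].
#' @examples
#' kineticsTable(
#'   isozymes = list(r1 = list(isozyme(c(g1 = 1), kcatFwd = 10))),
#'   masses = c(g1 = 1), lengths = c(g1 = 300),
#'   capacities = list(all = list(genes = "all", limit = 1)))
#' @export
kineticsTable <- function(isozymes = list(), masses = numeric(0),
                          lengths = integer(0), capacities = list()) {
  for (rid in names(isozymes)) {
    iso <- isozymes[[rid]]
    if (is(iso, "Isozyme")) isozymes[[rid]] <- list(iso)
    else stopifnot(all(vapply(iso, is, logical(1), class2 = "Isozyme")))
  }
  new("KineticsTable", isozymes = isozymes, masses = masses,
      lengths = stats::setNames(as.integer(lengths), names(lengths)),
      capacities = capacities)
}

.parseGeneStoich <- function(s) {
  ## "g1:2;g2:1" or "g1;g2" (counts default 1)
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty gene list in kinetics table")
  out <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    out[trimws(kv[[1]])] <- if (length(kv) > 1L) as.numeric(kv[[2]]) else 1
  }
  out
}

#' Read enzyme kinetics from TSV tables
#'
#' `isozymeFile` columns: `reaction`, `isozyme_id`, `genes` (semi-colon list
#' with optional `:count` subunit stoichiometry, e.g. `"g1:2;g2:1"`),
#' `kcat_fwd`, `kcat_rev` (1/h; empty or `NA` when absent).
#' `geneFile` columns: `gene`, `mass` (g/mmol), `length` (amino acids).
#' `capacityFile` (optional) columns: `group`, `genes` (`"all"` or a
#' semi-colon list), `limit` (g/gDW).
#'
#' @param isozymeFile,geneFile,capacityFile TSV paths; `capacityFile` may be
#'   `NULL`.
#' @return a [KineticsTable-class].
#' @export
readKineticsTsv <- function(isozymeFile, geneFile, capacityFile = NULL) {
  it <- utils::read.delim(isozymeFile, stringsAsFactors = FALSE)
  need <- c("reaction", "isozyme_id", "genes", "kcat_fwd", "kcat_rev")
  if (!all(need %in% names(it)))
    stop(sprintf("isozyme table needs columns: %s", paste(need, collapse = ", ")))
  isozymes <- list()
  for (i in seq_len(nrow(it))) {
    iso <- isozyme(.parseGeneStoich(it$genes[i]),
                   kcatFwd = suppressWarnings(as.numeric(it$kcat_fwd[i])),
                   kcatRev = suppressWarnings(as.numeric(it$kcat_rev[i])))
    rid <- it$reaction[i]
    isozymes[[rid]] <- c(isozymes[[rid]], list(iso))
  }
  gt <- utils::read.delim(geneFile, stringsAsFactors = FALSE)
  if (!all(c("gene", "mass", "length") %in% names(gt)))
    stop("gene table needs columns: gene, mass, length")
  caps <- list()
  if (!is.null(capacityFile)) {
    ct <- utils::read.delim(capacityFile, stringsAsFactors = FALSE)
    if (!all(c("group", "genes", "limit") %in% names(ct)))
      stop("capacity table needs columns: group, genes, limit")
    for (i in seq_len(nrow(ct))) {
      gspec <- trimws(ct$genes[i])
      caps[[ct$group[i]]] <- list(
        genes = if (identical(gspec, "all")) "all"
                else names(.parseGeneStoich(gspec)),
        limit = as.numeric(ct$limit[i]))
    }
  }
  kineticsTable(isozymes = isozymes,
                masses = stats::setNames(gt$mass, gt$gene),
                lengths = stats::setNames(gt$length, gt$gene),
                capacities = caps)
}

#' Read enzyme kinetics from a single JSON file
#'
#' Schema: object with keys `isozymes` (reaction id -> array of
#' `{genes: {id: count}, kcat_fwd, kcat_rev}`), `masses`, `lengths`
#' (gene id -> number), and `capacities` (group id ->
#' `{genes: [..] or "all", limit}`).
#'
#' @param file JSON path.
#' @return a [KineticsTable-class].
#' @export
readKineticsJson <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  isozymes <- lapply(doc$isozymes %||% list(), function(lst)
    lapply(lst, function(e)
      isozyme(vapply(e$genes, as.numeric, numeric(1)),
              kcatFwd = .jsonNum(e$kcat_fwd), kcatRev = .jsonNum(e$kcat_rev))))
  caps <- lapply(doc$capacities %||% list(), function(g)
    list(genes = if (identical(g$genes, "all")) "all" else unlist(g$genes),
         limit = as.numeric(g$limit)))
  kineticsTable(
    isozymes = isozymes,
    masses = vapply(doc$masses %||% list(), as.numeric, numeric(1)),
    lengths = vapply(doc$lengths %||% list(), as.numeric, numeric(1)),
    capacities = caps)
}

setMethod("show", "KineticsTable", function(object) {
  cat(sprintf("KineticsTable: %d reactions with isozymes, %d gene masses, %d capacity group(s)\n",
              length(object@isozymes), length(object@masses),
              length(object@capacities)))
})
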