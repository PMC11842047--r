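test_that("COBRA JSON reading handles minimal and malformed models", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(), genes = list(),
    reactions = list(list(id = "r1", lower_bound = 0, upper_bound = 5))),
    tmp, auto_unbox = TRUE)
  m <- readCobraJson(tmp)
  expect_equal(nrow(reactions(m)), 1L)
  expect_equal(nrow(metabolites(m)), 0L)
  expect_equal(reactions(m)$objective, 0)      # missing objective defaults 0

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(), genes = list(),
    reactions = list(list(id = "r1", lower_bound = 0, upper_bound = 5,
                          metabolites = list(ghost = -1)))),
    bad, auto_unbox = TRUE)
  expect_error(readCobraJson(bad), "unknown metabolite 'ghost'")
  expect_error(readCobraJson("does_not_exist.json"), "not found")
})

test_that("COBRA JSON survives a write/read round trip", {
  for (bundle in list(toyChainModel(10), toyDiamondModel())) {
    tmp <- withr::local_tempfile(fileext = ".json")
    writeCobraJson(bundle@model, tmp)
    back <- readCobraJson(tmp)
    expect_equal(reactions(back), reactions(bundle@model))
    expect_equal(metabolites(back), metabolites(bundle@model))
    expect_equal(as.matrix(stoichiometry(back)),
                 as.matrix(stoichiometry(bundle@model)))
    expect_equal(genes(back), genes(bundle@model))
    expect_equal(lapply(back@gprs, printGpr), lapply(bundle@model@gprs, printGpr))
  }
})

test_that("identifiers outside the label charset are sanitized with a log", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "glc[c]", compartment = "c"),
                       list(id = "glc(c)", compartment = "c")),
    genes = list(list(id = "b0001.v2")),
    reactions = list(list(id = "EX_glc(e)", lower_bound = -10, upper_bound = 0,
                          metabolites = list(`glc[c]` = -1),
                          gene_reaction_rule = "b0001.v2"))),
    tmp, auto_unbox = TRUE)
  m <- readCobraJson(tmp)
  expect_true(all(grepl("^[A-Za-z0-9_]+$", metabolites(m)$id)))
  expect_true(all(grepl("^[A-Za-z0-9_]+$", reactions(m)$id)))
  # both metabolites sanitize to the same stem; suffix keeps them unique
  expect_equal(anyDuplicated(metabolites(m)$id), 0L)
  expect_gt(nrow(m@sanitization), 0L)
  # GPR leaf renamed along with the gene
  expect_equal(printGpr(m@gprs[[1]]), genes(m)[[1]])
})

test_that("SBML core-FBC models load into the canonical form", {
  f <- system.file("extdata", "toy_chain.sbml.xml", package = "fluxtree")
  m <- readSbml(f)
  expect_equal(reactions(m)$id, c("r_in", "r_conv", "r_growth"))
  expect_equal(reactions(m)$upper, c(10, Inf, Inf))
  expect_equal(reactions(m)$objective, c(0, 0, 1))
  expect_equal(printGpr(m@gprs$r_conv), "g1")
  expect_equal(fluxBalanceAnalysis(fluxBalanceConstraints(m))$objective, 10,
               tolerance = 1e-9)
})

test_that("solution JSON mirrors the tree and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeSolutionJson(list(a = list(b = 1.5)), tmp)
  expect_equal(jsonlite::fromJSON(tmp)$a$b, 1.5)

  tree <- fluxBalanceConstraints(toyChainModel(10)@model)
  sol <- fluxBalanceAnalysis(tree)$solution
  writeSolutionJson(sol, tmp)
  back <- readSolutionJson(tmp)
  expect_equal(unlist(back), unlist(sol), tolerance = 1e-10)

  writeSolutionJson(list(), tmp)
  expect_identical(gsub("\\s", "", paste(readLines(tmp), collapse = "")), "{}")
  expect_error(writeSolutionJson(list(a = "text"), tmp), "numeric")
})

test_that("kinetics tables load from TSV and JSON", {
  iso <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction\tisozyme_id\tgenes\tkcat_fwd\tkcat_rev",
               "rA\tiso1\tgA:2;gB:1\t10\tNA",
               "rA\tiso2\tgC\t5\t2",
               "rB\tiso1\tgB\t7\tNA"), iso)
  gn <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmass\tlength", "gA\t40\t364", "gB\t30\t273", "gC\t50\t455"),
             gn)
  cp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group\tgenes\tlimit", "membrane\tgA;gB\t0.1", "all\tall\t0.5"), cp)
  k <- readKineticsTsv(iso, gn, cp)
  expect_equal(length(k@isozymes$rA), 2L)
  expect_equal(k@isozymes$rA[[1]]@geneStoichiometry, c(gA = 2, gB = 1))
  expect_equal(k@isozymes$rA[[2]]@kcatRev, 2)
  expect_true(is.na(k@isozymes$rB[[1]]@kcatRev))
  expect_equal(k@masses[["gB"]], 30)
  expect_equal(k@lengths[["gC"]], 455L)
  expect_equal(k@capacities$membrane$genes, c("gA", "gB"))
  expect_equal(k@capacities$all$genes, "all")

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    isozymes = list(rA = list(list(genes = list(gA = 2, gB = 1), kcat_fwd = 10))),
    masses = list(gA = 40, gB = 30), lengths = list(gA = 364, gB = 273),
    capacities = list(all = list(genes = "all", limit = 0.5))),
    js, auto_unbox = TRUE)
  kj <- readKineticsJson(js)
  expect_equal(kj@isozymes$rA[[1]]@geneStoichiometry, c(gA = 2, gB = 1))
  expect_equal(kj@capacities$all$limit, 0.5)
})
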