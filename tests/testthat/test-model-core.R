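# Model construction, validation, serialisation and medium handling.

test_that("constructor reports counts and validates stoichiometry", {
  m <- chainModel()
  expect_equal(length(reactionIds(m)), 3)
  expect_equal(length(metaboliteIds(m)), 2)
  expect_identical(biomassReaction(m), "BIOMASS")
  # undeclared metabolite is refused, naming the offending reaction
  expect_error(MetabolicModel(
    metabolites = data.frame(id = "A"),
    reactions = list(RX = list(stoich = c(A = -1, X = 1), lb = 0, ub = 1)),
    biomass = "RX"), "RX.*X")
  # invalid bounds are refused
  bad <- chainModel()
  expect_error({ bad@lb["R1"] <- 5; bad@ub["R1"] <- 1; validObject(bad) },
               "lower bound exceeds upper bound")
  expect_error(MetabolicModel(
    metabolites = data.frame(id = "A"),
    reactions = list(EX_A = list(stoich = c(A = -1), lb = 0, ub = 1)),
    biomass = "NOPE"), "biomass")
})

test_that("JSON round trip preserves every field", {
  m <- generateToyModel(syntheticSpec(seed = 11))$model
  path <- withr::local_tempfile(fileext = ".json")
  writeModel(m, path, "json")
  m2 <- readModel(path, "json")
  expect_identical(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m)))
  expect_identical(m2@lb, m@lb)
  expect_identical(m2@ub, m@ub)
  expect_identical(vapply(gprRules(m2), function(g) g@text, ""),
                   vapply(gprRules(m), function(g) g@text, ""))
  expect_identical(m2@subsystem, m@subsystem)
  expect_identical(geneIds(m2), geneIds(m))
  expect_identical(biomassReaction(m2), biomassReaction(m))
  # empty GPRs are omitted from the file, not written as empty strings
  doc <- jsonlite::read_json(path)
  ex <- Filter(function(r) r$id == "EX_M0", doc$reactions)[[1]]
  expect_null(ex$gpr)
})

test_that("SBML round trip preserves every field", {
  m <- generateToyModel(syntheticSpec(seed = 12))$model
  path <- withr::local_tempfile(fileext = ".xml")
  writeModel(m, path, "sbml")
  m2 <- readModel(path, "sbml")
  expect_identical(as.matrix(stoichiometry(m2))[metaboliteIds(m), ],
                   as.matrix(stoichiometry(m)))
  expect_identical(m2@lb, m@lb)
  expect_identical(m2@ub, m@ub)
  expect_identical(vapply(gprRules(m2), function(g) g@text, ""),
                   vapply(gprRules(m), function(g) g@text, ""))
  expect_identical(m2@subsystem, m@subsystem)
  expect_setequal(geneIds(m2), geneIds(m))
  expect_identical(biomassReaction(m2), biomassReaction(m))
  # the file has one reaction entry per model reaction
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  expect_length(xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns),
                length(reactionIds(m)))
})

test_that("JSON reader rejects a reaction consuming an undeclared metabolite", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [{"id": "RBAD", "stoich": {"A": -1, "X": 1},
                   "lb": 0, "ub": 10}],
    "biomass": "RBAD"
  }', path)
  expect_error(readModel(path, "json"), "RBAD.*X")
})

test_that("exchange detection and gene lookup work", {
  m <- decoyModel()
  expect_setequal(exchangeReactions(m), c("EX_A", "EX_W", "EX_Z"))
  m2 <- MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = list(
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1, gpr = "G1 or G2"),
      R2 = list(stoich = c(B = -1, C = 1), lb = 0, ub = 1, gpr = "G2 and G3"),
      R3 = list(stoich = c(C = -1), lb = 0, ub = 1)),
    biomass = "R3")
  expect_setequal(genesOfReactions(m2, c("R1", "R2")), c("G1", "G2", "G3"))
  expect_identical(genesOfReactions(m2, "R3"), character(0))
  expect_identical(genesOfReactions(m2, character(0)), character(0))
  expect_error(genesOfReactions(m2, "NOPE"), "unknown reaction")
})

test_that("applyMedium sets uptake bounds and touches nothing else", {
  m <- decoyModel()
  med <- Medium(c(EX_A = 7))
  m2 <- applyMedium(m, med)
  expect_equal(unname(m2@lb["EX_A"]), -7)
  # exchanges absent from the medium are closed for uptake
  expect_equal(unname(m2@lb["EX_W"]), 0)
  # secretion bounds and non-exchange reactions unchanged
  expect_identical(m2@ub, m@ub)
  expect_identical(m2@lb[c("R1", "RD", "BIOMASS")],
                   m@lb[c("R1", "RD", "BIOMASS")])
  expect_identical(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m)))
  # the input model is not modified
  expect_equal(unname(m@lb["EX_A"]), -10)
  # naming an internal reaction is an error
  expect_error(applyMedium(m, Medium(c(R1 = 5))), "non-exchange")
  # negative magnitudes are refused at construction
  expect_error(Medium(c(EX_A = -1)), "nonnegative")
})

test_that("medium TSV round trip", {
  med <- Medium(c(EX_A = 10, EX_W = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMedium(med, path)
  expect_identical(readMedium(path)@uptake, med@uptake)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("foo\tbar\nEX_A\t1", bad)
  expect_error(readMedium(bad), "exchange_reaction_id")
})

test_that("subsetModel drops orphaned metabolites and keeps bounds", {
  m <- decoyModel()
  s <- subsetModel(m, c("EX_A", "R1", "BIOMASS"))
  expect_setequal(reactionIds(s), c("EX_A", "R1", "BIOMASS"))
  expect_setequal(metaboliteIds(s), c("A", "B"))
  expect_identical(s@lb, m@lb[reactionIds(s)])
  expect_identical(biomassReaction(s), "BIOMASS")
})
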