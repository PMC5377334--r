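# Synthetic bundle generation: determinism, planted structure, and
# recoverability of the planted signals in the zero-noise limit.

test_that("generation is a pure function of the spec", {
  spec <- syntheticSpec(seed = 9)
  b1 <- generateBundle(spec)
  b2 <- generateBundle(spec)
  expect_identical(as.matrix(stoichiometry(b1$model)),
                   as.matrix(stoichiometry(b2$model)))
  expect_identical(SummarizedExperiment::assay(b1$expression),
                   SummarizedExperiment::assay(b2$expression))
  expect_identical(b1$metabolome@conc, b2$metabolome@conc)
  expect_identical(b1$network@edges, b2$network@edges)
  expect_identical(b1$truth, b2$truth)
  # a different seed changes the expression draw
  b3 <- generateBundle(syntheticSpec(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(b1$expression),
                         SummarizedExperiment::assay(b3$expression)))
  # generators leave the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(generateBundle(spec))
  expect_identical(.Random.seed, before)
})

test_that("the toy model has the planted structure and grows", {
  spec <- syntheticSpec(seed = 2, nDecoy = 4)
  toy <- generateToyModel(spec)
  expect_length(toy$truth$decoyReactions, 4)
  expect_length(setdiff(toy$truth$coupledReactions, "BIOMASS"), spec@nCoupled)
  g <- fba(applyMedium(toy$model, toy$medium))
  expect_identical(g@status, "optimal")
  expect_gt(g@objective, 0)
  # every coupled reaction's GPR references at least one planted-up gene
  for (r in setdiff(toy$truth$coupledReactions, "BIOMASS")) {
    gs <- gprRules(toy$model)[[r]]@genes
    expect_gt(length(intersect(gs, toy$truth$plantedUp)), 0)
  }
  # decoys are flux-feasible but bounded independently of biomass
  rng <- fva(applyMedium(toy$model, toy$medium), fraction = 1)
  for (r in toy$truth$decoyReactions) {
    expect_equal(rng$max[rng$reaction == r], 5, tolerance = 1e-6)
    expect_equal(rng$min[rng$reaction == r], 0, tolerance = 1e-6)
  }
})

test_that("the bundle's model passes its own task list", {
  b <- generateBundle(syntheticSpec(seed = 6))
  chk <- checkTasks(b$model, b$tasks)
  expect_true(all(chk$ok))
})

test_that("zero noise makes DE recover exactly the planted sets", {
  spec <- syntheticSpec(seed = 4, noiseSd = 0)
  b <- generateBundle(spec)
  de <- differentialExpression(b$expression, "CD133pos", "CD133neg")
  expect_setequal(de$gene[de$call == "up"], b$truth$plantedUp)
  expect_setequal(de$gene[de$call == "down"], b$truth$plantedDown)
})

test_that("unit effect size plants nothing callable at zero noise", {
  spec <- syntheticSpec(seed = 4, noiseSd = 0, effectSize = 1)
  b <- generateBundle(spec)
  de <- differentialExpression(b$expression, "CD133pos", "CD133neg")
  expect_identical(unique(de$call), "ns")
})

test_that("the metabolome realises planted fold changes and dropouts", {
  b <- generateBundle(syntheticSpec(seed = 8))
  fc <- metaboliteFoldChanges(b$metabolome, "CD133pos", "CD133neg")
  expect_true(fc$flagged[fc$metabolite == "met_M1"])   # planted FC 3
  expect_gt(fc$fc[fc$metabolite == "met_M1"], 1.5)
  expect_false(fc$flagged[fc$metabolite == "met_M2"])  # planted FC 1
  cls <- classifyDetection(b$metabolome, "CD133pos", "CD133neg")
  got <- setNames(cls$category, cls$metabolite)
  expect_identical(unname(got["met_dropA"]), "A_only")
  expect_identical(unname(got["met_dropB"]), "B_only")
  expect_identical(unname(got["met_none"]), "neither")
  expect_identical(unname(got["met_irre"]), "irreproducible")
})

test_that("the regulatory network plants one master and disjoint decoys", {
  spec <- syntheticSpec(seed = 3)
  b <- generateBundle(spec)
  tg <- b$network@targets
  expect_setequal(tg$TF_master, b$truth$coupledGenes)
  decoyTfs <- setdiff(names(tg), "TF_master")
  expect_length(decoyTfs, spec@nTfs - 1)
  for (tf in decoyTfs)
    expect_length(intersect(tg[[tf]], b$truth$coupledGenes), 0)
  expect_true(all(b$network@edges$confidence == "High"))
})

test_that("written bundles reload consistently", {
  b <- generateBundle(syntheticSpec(seed = 13))
  dir <- withr::local_tempdir()
  writeBundle(b, dir)
  m <- readModel(file.path(dir, "model.json"))
  expect_identical(sort(reactionIds(m)), sort(reactionIds(b$model)))
  tasks <- readTasks(file.path(dir, "tasks.json"))
  expect_identical(vapply(tasks, function(t) t@id, ""),
                   vapply(b$tasks, function(t) t@id, ""))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$coupledReactions, b$truth$coupledReactions)
  nw <- loadRegulatoryNetwork(file.path(dir, "network.tsv"), "High")
  expect_identical(nw@edges, b$network@edges)
})
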