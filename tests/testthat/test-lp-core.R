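# Flux balance / flux variability analysis against closed forms and the
# vertex-enumeration oracle.

test_that("FBA solves the single-path chain and reports infeasibility", {
  m <- chainModel(uptake = 10)
  r <- fba(m)
  expect_identical(r@status, "optimal")
  expect_equal(r@objective, 10, tolerance = 1e-9)
  # steady state holds for the reported fluxes
  expect_lt(max(abs(as.matrix(stoichiometry(m)) %*% r@fluxes)), 1e-8)
  m2 <- m
  m2@lb["EX_A"] <- 0; m2@ub["EX_A"] <- 0; m2@lb["BIOMASS"] <- 1
  r2 <- fba(m2)
  expect_identical(r2@status, "infeasible")
  expect_length(r2@fluxes, 0)
})

test_that("FBA picks the high-yield branch (vertex oracle)", {
  m <- branchedModel(uptake = 10)
  r <- fba(m)
  expect_equal(r@objective, oracleFBA(m), tolerance = 1e-6)
  expect_equal(r@objective, 10, tolerance = 1e-9)
  expect_equal(unname(r@fluxes["R1"]), 10, tolerance = 1e-6)
  expect_equal(unname(r@fluxes["R2"]), 0, tolerance = 1e-6)
})

test_that("FBA optimum equals the vertex-enumeration maximum on all fixtures", {
  fixtures <- list(chainModel(), longChainModel(3), branchedModel(),
                   diamondModel(), deadEndModel(), decoyModel())
  for (m in fixtures) {
    for (dir in c("max", "min")) {
      r <- fba(m, direction = dir)
      expect_identical(r@status, "optimal")
      expect_equal(r@objective, oracleFBA(m, direction = dir),
                   tolerance = 1e-6)
    }
  }
})

test_that("FVA matches the oracle on the diamond and the chain", {
  m <- diamondModel(uptake = 10)
  rng <- fva(m, fraction = 1)
  expect_equal(rng$min[rng$reaction == "R2"], 0, tolerance = 1e-6)
  expect_equal(rng$max[rng$reaction == "R2"], 10, tolerance = 1e-6)
  expect_equal(rng$min[rng$reaction == "R3"], 0, tolerance = 1e-6)
  expect_equal(rng$max[rng$reaction == "R3"], 10, tolerance = 1e-6)
  orc <- oracleFVA(m, fraction = 1)
  expect_equal(rng$min, orc$min, tolerance = 1e-6)
  expect_equal(rng$max, orc$max, tolerance = 1e-6)

  ch <- chainModel(uptake = 10)
  rng9 <- fva(ch, fraction = 0.9)
  for (r in c("R1", "BIOMASS")) {
    expect_equal(rng9$min[rng9$reaction == r], 9, tolerance = 1e-6)
    expect_equal(rng9$max[rng9$reaction == r], 10, tolerance = 1e-6)
  }
  orc9 <- oracleFVA(ch, fraction = 0.9)
  expect_equal(rng9$min, orc9$min, tolerance = 1e-6)
  expect_equal(rng9$max, orc9$max, tolerance = 1e-6)
  # fixed mode pins the objective
  rngF <- fva(ch, fraction = 0.9, mode = "fixed")
  expect_equal(rngF$min[rngF$reaction == "R1"], 9, tolerance = 1e-6)
  expect_equal(rngF$max[rngF$reaction == "R1"], 9, tolerance = 1e-6)
})

test_that("a [0,0]-bounded disconnected reaction has FVA range [0,0]", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "X", "Y")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -10, ub = 0),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      RZ = list(stoich = c(X = -1, Y = 1), lb = 0, ub = 0),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
  rng <- fva(m, fraction = 1)
  expect_equal(rng$min[rng$reaction == "RZ"], 0)
  expect_equal(rng$max[rng$reaction == "RZ"], 0)
})

test_that("FVA ranges are monotone in the objective fraction", {
  m <- diamondModel()
  prev <- fva(m, fraction = 0)
  for (f in c(0.5, 0.9, 1)) {
    cur <- fva(m, fraction = f)
    expect_true(all(cur$min >= prev$min - 1e-9))
    expect_true(all(cur$max <= prev$max + 1e-9))
    prev <- cur
  }
})

test_that("scaling all bounds by k scales the FBA optimum by k", {
  for (m in list(chainModel(), branchedModel(), decoyModel())) {
    base <- fba(m)@objective
    for (k in c(0.5, 2, 7)) {
      ms <- m
      ms@lb <- ms@lb * k
      ms@ub <- ms@ub * k
      expect_equal(fba(ms)@objective, k * base, tolerance = 1e-8)
    }
  }
})

test_that("blocked reactions are exactly the mass-balance-forced zeros", {
  expect_identical(blockedReactions(deadEndModel()), "RX")
  expect_identical(blockedReactions(chainModel()), character(0))
})

test_that("unbounded problems are flagged, not fabricated", {
  m <- chainModel()
  m@lb["EX_A"] <- -Inf; m@ub["EX_A"] <- Inf
  m@ub["R1"] <- Inf; m@ub["BIOMASS"] <- Inf
  expect_identical(fba(m)@status, "unbounded")
})
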