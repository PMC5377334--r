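# Small fixture models built in code.  Sign convention: exchanges are
# written "met ->", so uptake is negative flux.

# EX_A -> R1 -> BIOMASS, uptake capped at `uptake`
chainModel <- function(uptake = 10) {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -uptake, ub = 1000),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000, gpr = "G1"),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}

# longer chain with per-step genes
longChainModel <- function(n = 4, uptake = 10) {
  mets <- data.frame(id = paste0("M", 0:n))
  rx <- list(EX_M0 = list(stoich = c(M0 = -1), lb = -uptake, ub = 1000))
  for (i in seq_len(n)) {
    st <- stats::setNames(c(-1, 1), paste0("M", c(i - 1, i)))
    rx[[paste0("R", i)]] <- list(stoich = st, lb = 0, ub = 1000,
                                 gpr = paste0("G", i))
  }
  rx$BIOMASS <- list(stoich = stats::setNames(-1, paste0("M", n)),
                     lb = 0, ub = 1000)
  MetabolicModel(mets, rx, biomass = "BIOMASS")
}

# two parallel routes A -> B with yields 1.0 (R1) and 0.5 (R2)
branchedModel <- function(uptake = 10) {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -uptake, ub = 0),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      R2 = list(stoich = c(A = -1, B = 0.5), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}

# diamond: A -> B via R2 or R3, both unbounded up to 1000
diamondModel <- function(uptake = 10) {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -uptake, ub = 0),
      R2 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      R3 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}

# chain plus a dead-end branch A -> X with no consumer of X
deadEndModel <- function() {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "X")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -10, ub = 10),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      RX = list(stoich = c(A = -1, X = 1), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}

# chain plus an isolated capped side path (EX_W -> RD -> EX_Z),
# flux-feasible but independent of biomass
decoyModel <- function() {
  MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "W", "Z")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -10, ub = 1000),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000),
      EX_W = list(stoich = c(W = -1), lb = -5, ub = 1000),
      RD = list(stoich = c(W = -1, Z = 1), lb = 0, ub = 5),
      EX_Z = list(stoich = c(Z = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
}

# two alternative routes P (A->B->C) and Q (A->D->C) feeding biomass;
# per-reaction weights are attached as an attribute
twoRouteFixture <- function(wP = 1, wQ = -0.5) {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "C", "D")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -10, ub = 1000),
      P1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      P2 = list(stoich = c(B = -1, C = 1), lb = 0, ub = 1000),
      Q1 = list(stoich = c(A = -1, D = 1), lb = 0, ub = 1000),
      Q2 = list(stoich = c(D = -1, C = 1), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(C = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
  w <- c(EX_A = 0, P1 = wP, P2 = wP, Q1 = wQ, Q2 = wQ, BIOMASS = 0)
  attr(m, "weights") <- w
  m
}

# gap-fill fixture: universal chain with several redundant bypasses;
# sub-model misses the middle of the chain
gapfillFixture <- function() {
  universal <- MetabolicModel(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = list(
      EX_A = list(stoich = c(A = -1), lb = -10, ub = 1000),
      R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
      R2 = list(stoich = c(B = -1, C = 1), lb = 0, ub = 1000),
      # direct bypass: one reaction replaces R1+R2
      RB = list(stoich = c(A = -1, C = 1), lb = 0, ub = 1000),
      # two-step detour with poor yield
      RD1 = list(stoich = c(A = -1, B = 0.5), lb = 0, ub = 1000),
      BIOMASS = list(stoich = c(C = -1), lb = 0, ub = 1000)),
    biomass = "BIOMASS")
  list(universal = universal,
       medium = Medium(c(EX_A = 10)))
}
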