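#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

#' Gene-protein-reaction (GPR) rule
#'
#' Boolean expression over gene identifiers with AND/OR connectives.
#' An isoenzyme set is written with OR, an enzyme complex with AND.  The
#' empty rule (no gene association) is a distinguished value: reactions
#' carrying it are treated as gene-independent throughout.
#'
#' @slot expr parsed expression tree: either \code{NULL} (empty rule), a
#'   character scalar (gene leaf), or \code{list(op =, args = list(...))}
#'   with \code{op} one of \code{"and"}, \code{"or"}.
#' @slot genes character vector of gene ids appearing in the rule.
#' @slot text the normalised textual form of the rule.
#' @export
setClass("GprRule", representation(expr = "ANY",
                                   genes = "character",
                                   text = "character"))

setValidity("GprRule", function(object) {
  leaves <- function(e) {
    if (is.null(e)) character(0)
    else if (is.character(e)) e
    else unlist(lapply(e$args, leaves))
  }
  lv <- leaves(object@expr)
  if (!setequal(lv, object@genes))
    return("gene set does not match the leaves of the expression tree")
  TRUE
})

#' Constraint-based metabolic model
#'
#' A stoichiometric model: metabolites, reactions with flux bounds and
#' GPR rules, and a designated biomass reaction.  Reversibility is
#' encoded purely by a negative lower bound.  Exchange reactions are the
#' single-metabolite boundary reactions, written in the secretion
#' direction ("met ->"): positive flux secretes, negative flux takes up.
#'
#' @slot mets data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @slot S sparse stoichiometric matrix (metabolites x reactions) with
#'   dimnames.
#' @slot lb,ub named numeric flux bounds per reaction
#'   (mmol/gDW/h by convention).
#' @slot gpr named list of \linkS4class{GprRule}, one per reaction.
#' @slot subsystem named character, subsystem label per reaction.
#' @slot genes character vector: the model's gene universe.
#' @slot biomass id of the biomass reaction.
#' @export
setClass("MetabolicModel", representation(mets = "data.frame",
                                          S = "Matrix",
                                          lb = "numeric",
                                          ub = "numeric",
                                          gpr = "list",
                                          subsystem = "character",
                                          genes = "character",
                                          biomass = "character"))

setValidity("MetabolicModel", function(object) {
  rid <- colnames(object@S)
  if (!identical(rownames(object@S), object@mets$id))
    return("S row names must equal metabolite ids")
  if (anyDuplicated(rid)) return("duplicate reaction ids")
  if (anyDuplicated(object@mets$id)) return("duplicate metabolite ids")
  for (nm in c("lb", "ub", "subsystem"))
    if (!identical(names(slot(object, nm)), rid))
      return(sprintf("'%s' must be named by the reaction ids", nm))
  if (!identical(names(object@gpr), rid))
    return("'gpr' must be named by the reaction ids")
  if (any(object@lb > object@ub))
    return(sprintf("lower bound exceeds upper bound for reaction '%s'",
                   rid[which(object@lb > object@ub)[1]]))
  if (length(object@biomass) != 1 || !(object@biomass %in% rid))
    return("biomass reaction id not found among the reactions")
  gg <- unique(unlist(lapply(object@gpr, function(g) g@genes)))
  if (!all(gg %in% object@genes))
    return(sprintf("GPR references undeclared gene(s): %s",
                   paste(setdiff(gg, object@genes), collapse = ", ")))
  TRUE
})

#' Growth medium
#'
#' Maximum uptake magnitudes for exchange reactions
#' (mmol/gDW/h, nonnegative).  Applying a medium sets each exchange
#' reaction's uptake bound to minus its magnitude; exchanges absent from
#' the medium are closed for uptake.
#'
#' @slot uptake named nonnegative numeric, exchange reaction id ->
#'   maximum uptake magnitude.
#' @export
setClass("Medium", representation(uptake = "numeric"))

setValidity("Medium", function(object) {
  if (length(object@uptake) && is.null(names(object@uptake)))
    return("uptake vector must be named by exchange reaction ids")
  if (any(object@uptake < 0)) return("uptake magnitudes must be nonnegative")
  TRUE
})

#' Flux balance analysis result
#'
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @slot objective optimal objective flux (NA unless optimal).
#' @slot fluxes named flux vector (empty unless optimal).
#' @export
setClass("FluxResult", representation(status = "character",
                                      objective = "numeric",
                                      fluxes = "numeric"))

#' Metabolic task
#'
#' A capability check: with only the allowed inputs open, each required
#' output must be producible at at least its minimum rate.  Tasks with
#' \code{shouldFail = TRUE} must NOT pass (negative controls for leaky
#' networks).
#'
#' @slot id,description character scalars.
#' @slot inputs named nonnegative numeric, metabolite id -> max uptake.
#' @slot outputs named nonnegative numeric, metabolite id -> min production.
#' @slot shouldFail logical scalar.
#' @export
setClass("MetabolicTask", representation(id = "character",
                                         description = "character",
                                         inputs = "numeric",
                                         outputs = "numeric",
                                         shouldFail = "logical"))

setValidity("MetabolicTask", function(object) {
  if (any(object@inputs < 0) || any(object@outputs < 0))
    return("task bounds must be nonnegative")
  if (length(object@outputs) == 0) return("task must require at least one output")
  TRUE
})

#' Context-specific model extraction result
#'
#' @slot model the extracted \linkS4class{MetabolicModel}.
#' @slot objective MILP objective (sum of weights over kept reactions).
#' @slot weights named numeric inclusion weights used.
#' @slot kept named logical over the universal reactions.
#' @slot fluxes certifying flux vector (universal reaction space).
#' @slot status solver status.
#' @export
setClass("ExtractionResult", representation(model = "MetabolicModel",
                                            objective = "numeric",
                                            weights = "numeric",
                                            kept = "logical",
                                            fluxes = "numeric",
                                            status = "character"))

#' Gap-filling result
#'
#' @slot added ids of universal reactions added (minimum cardinality).
#' @slot growth biomass flux achieved after addition.
#' @slot status solver status.
#' @export
setClass("GapfillResult", representation(added = "character",
                                         growth = "numeric",
                                         status = "character"))

#' Flux-response scan result
#'
#' For each biomass fraction f the biomass flux is enforced and a flux
#' variability analysis is run; the midpoint (min+max)/2 of each
#' reaction's range is recorded and correlated (Pearson) with the
#' biomass flux series.
#'
#' @slot fractions increasing fractions of the biomass optimum scanned.
#' @slot biomassFlux enforced biomass flux at each fraction.
#' @slot means reactions x fractions matrix of FVA midpoints.
#' @slot r named Pearson correlations (0 sentinel for constant series).
#' @slot muMax unconstrained biomass optimum.
#' @slot mode "fixed" (equality per step) or "lower_bound".
#' @export
setClass("GrowthAssociationResult", representation(fractions = "numeric",
                                                   biomassFlux = "numeric",
                                                   means = "matrix",
                                                   r = "numeric",
                                                   muMax = "numeric",
                                                   mode = "character"))

setValidity("GrowthAssociationResult", function(object) {
  if (ncol(object@means) != length(object@fractions))
    return("mean-flux series length must equal the number of fractions")
  if (length(object@biomassFlux) != length(object@fractions))
    return("biomass series length must equal the number of fractions")
  ok <- is.na(object@r) | (object@r >= -1 - 1e-9 & object@r <= 1 + 1e-9)
  if (!all(ok)) return("Pearson r outside [-1, 1]")
  TRUE
})

#' Metabolome concentration table
#'
#' Replicate concentrations for two cell types.  "standard" metabolites
#' carry absolute concentrations (pmol per 10^6 cells); "putative"
#' metabolites carry unitless relative areas.  A missing value (NA)
#' means the metabolite was not detected in that replicate.
#'
#' @slot conc metabolites x replicate-columns matrix; NA = not detected.
#' @slot metClass named character, "standard" or "putative" per metabolite.
#' @slot cellType character per column: the cell-type label of each
#'   replicate column.
#' @export
setClass("MetabolomeTable", representation(conc = "matrix",
                                           metClass = "character",
                                           cellType = "character"))

setValidity("MetabolomeTable", function(object) {
  empty <- nrow(object@conc) == 0 && length(object@metClass) == 0
  if (!empty && !identical(names(object@metClass), rownames(object@conc)))
    return("metClass must be named by the metabolite rownames")
  if (!all(object@metClass %in% c("standard", "putative")))
    return("metabolite class must be 'standard' or 'putative'")
  if (length(object@cellType) != ncol(object@conc))
    return("cellType must have one label per replicate column")
  TRUE
})

#' Regulatory network (TF -> target edges)
#'
#' @slot edges data.frame with columns TF, target, confidence, evidence;
#'   duplicate (TF, target) pairs are collapsed on construction.
#' @slot targets named list: TF id -> character vector of target genes.
#' @export
setClass("RegulatoryNetwork", representation(edges = "data.frame",
                                             targets = "list"))

setValidity("RegulatoryNetwork", function(object) {
  need <- c("TF", "target", "confidence", "evidence")
  if (!all(need %in% colnames(object@edges)))
    return("edges must have columns TF, target, confidence, evidence")
  if (anyDuplicated(object@edges[, c("TF", "target")]))
    return("duplicate (TF, target) edges")
  if (any(!nzchar(object@edges$TF)) || any(!nzchar(object@edges$target)))
    return("empty TF or target id")
  TRUE
})

#' Synthetic-data generator specification
#'
#' Defines the study conditions that the synthetic bundle emulates:
#' duplicate microarray-like expression for two cell types with planted
#' >= effectSize fold changes, a toy biomass-producing network with
#' growth-coupled and decoy reactions, a metabolome with detection
#' dropouts, and a regulatory network with one planted master regulator.
#' The seed fully determines every generated output.
#'
#' @slot seed integer RNG seed.
#' @slot nCoupled length of the growth-coupled linear pathway (reactions).
#' @slot nDecoy number of growth-decoupled decoy reactions.
#' @slot nGenes total gene pool size.
#' @slot nPlantedUp,nPlantedDown planted differentially expressed genes.
#' @slot effectSize planted fold change (default 2).
#' @slot noiseSd lognormal noise scale (sdlog, default 0.1).
#' @slot replicates samples per group (default 2, duplicate arrays).
#' @slot nTfs number of transcription factors (1 master + decoys).
#' @slot masterCoverage fraction of coupled genes targeted by the master
#'   TF (default 1).
#' @export
setClass("SyntheticSpec", representation(seed = "integer",
                                         nCoupled = "integer",
                                         nDecoy = "integer",
                                         nGenes = "integer",
                                         nPlantedUp = "integer",
                                         nPlantedDown = "integer",
                                         effectSize = "numeric",
                                         noiseSd = "numeric",
                                         replicates = "integer",
                                         nTfs = "integer",
                                         masterCoverage = "numeric"))

setValidity("SyntheticSpec", function(object) {
  cnt <- c(object@nCoupled, object@nDecoy, object@nGenes, object@nPlantedUp,
           object@nTfs, object@replicates)
  if (any(cnt <= 0)) return("all counts must be positive")
  if (object@nPlantedDown < 0) return("nPlantedDown must be >= 0")
  if (object@effectSize < 1) return("effectSize must be >= 1")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (object@masterCoverage <= 0 || object@masterCoverage > 1)
    return("masterCoverage must be in (0, 1]")
  if (object@nPlantedUp < object@nCoupled)
    return("planted up set must cover the coupled pathway genes")
  if (object@nGenes < object@nPlantedUp + object@nPlantedDown + object@nDecoy)
    return("gene pool too small for the planted sets")
  TRUE
})
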