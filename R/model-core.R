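#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (missing name/compartment are filled with the id
#'   and \code{"c"}).
#' @param reactions named list: reaction id -> list with elements
#'   \code{stoich} (named numeric, metabolite -> coefficient),
#'   \code{lb}, \code{ub}, optional \code{gpr} (rule text or
#'   \linkS4class{GprRule}) and \code{subsystem}.
#' @param biomass id of the biomass reaction.
#' @param genes optional gene universe; defaults to the union of GPR genes.
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' m <- MetabolicModel(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = list(
#'     EX_A = list(stoich = c(A = -1), lb = -10, ub = 1000),
#'     R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000, gpr = "G1"),
#'     BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
#'   biomass = "BIOMASS")
#' @export
MetabolicModel <- function(metabolites, reactions, biomass, genes = NULL) {
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(mets)) stop("metabolites need an 'id' column")
  if (!"name" %in% colnames(mets)) mets$name <- mets$id
  if (!"compartment" %in% colnames(mets)) mets$compartment <- "c"
  mets <- mets[, c("id", "name", "compartment")]
  rownames(mets) <- NULL

  rids <- names(reactions)
  if (is.null(rids) || any(!nzchar(rids))) stop("reactions must be a named list")
  triplets <- list(i = integer(0), j = integer(0), x = numeric(0))
  lb <- ub <- numeric(length(reactions))
  gpr <- vector("list", length(reactions))
  subsystem <- character(length(reactions))
  for (k in seq_along(reactions)) {
    r <- reactions[[k]]
    st <- r$stoich
    bad <- setdiff(names(st), mets$id)
    if (length(bad))
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   rids[k], paste(bad, collapse = ", ")))
    triplets$i <- c(triplets$i, match(names(st), mets$id))
    triplets$j <- c(triplets$j, rep(k, length(st)))
    triplets$x <- c(triplets$x, unname(st))
    lb[k] <- r$lb; ub[k] <- r$ub
    g <- r$gpr
    gpr[[k]] <- if (is.null(g)) emptyGpr()
                else if (is(g, "GprRule")) g
                else parseGpr(g)
    subsystem[k] <- if (is.null(r$subsystem)) "" else r$subsystem
  }
  S <- Matrix::sparseMatrix(i = triplets$i, j = triplets$j, x = triplets$x,
                            dims = c(nrow(mets), length(reactions)),
                            dimnames = list(mets$id, rids))
  names(lb) <- names(ub) <- names(gpr) <- names(subsystem) <- rids
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(gpr, function(g) g@genes))))
  new("MetabolicModel", mets = mets, S = S, lb = lb, ub = ub, gpr = gpr,
      subsystem = subsystem, genes = genes, biomass = biomass)
}

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(model) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(model) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(model) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("biomassReaction", function(model) standardGeneric("biomassReaction"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(model) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("bounds", function(model) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setGeneric("gprRules", function(model) standardGeneric("gprRules"))
#' @rdname accessors
#' @export
setGeneric("exchangeReactions", function(model) standardGeneric("exchangeReactions"))

#' Model accessors
#'
#' Read-only views on a \linkS4class{MetabolicModel}: reaction /
#' metabolite / gene identifiers, the biomass reaction id, the sparse
#' stoichiometric matrix, the flux bounds (data.frame with lb/ub), the
#' GPR rule list, and the exchange reactions (single-metabolite boundary
#' reactions, secretion-positive convention).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @name accessors
NULL

#' @rdname accessors
setMethod("reactionIds", "MetabolicModel", function(model) colnames(model@S))
#' @rdname accessors
setMethod("metaboliteIds", "MetabolicModel", function(model) model@mets$id)
#' @rdname accessors
setMethod("geneIds", "MetabolicModel", function(model) model@genes)
#' @rdname accessors
setMethod("biomassReaction", "MetabolicModel", function(model) model@biomass)
#' @rdname accessors
setMethod("stoichiometry", "MetabolicModel", function(model) model@S)
#' @rdname accessors
setMethod("bounds", "MetabolicModel", function(model)
  data.frame(reaction = colnames(model@S), lb = unname(model@lb),
             ub = unname(model@ub)))
#' @rdname accessors
setMethod("gprRules", "MetabolicModel", function(model) model@gpr)
#' @rdname accessors
setMethod("exchangeReactions", "MetabolicModel", function(model) {
  nnz <- Matrix::colSums(model@S != 0)
  ## the biomass drain is a pseudo-reaction, not a boundary exchange
  setdiff(colnames(model@S)[nnz == 1], model@biomass)
})

#' @export
setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", ncol(object@S), "reactions,", nrow(object@S),
      "metabolites,", length(object@genes), "genes\n")
  cat("  biomass:", object@biomass, "| exchanges:",
      length(exchangeReactions(object)), "\n")
})

#' @export
setMethod("show", "Medium", function(object) {
  cat("Medium with", length(object@uptake), "uptake bound(s)\n")
})

#' Construct a growth medium
#'
#' @param uptake named nonnegative numeric: exchange reaction id ->
#'   maximum uptake magnitude (mmol/gDW/h).
#' @return a \linkS4class{Medium}.
#' @export
Medium <- function(uptake = numeric(0)) {
  new("Medium", uptake = uptake)
}

#' Read a medium definition from TSV
#'
#' Two-column tab-separated file with header:
#' \code{exchange_reaction_id}, \code{max_uptake}.
#'
#' @param path file path.
#' @return a \linkS4class{Medium}.
#' @export
readMedium <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exchange_reaction_id", "max_uptake")
  if (!all(need %in% colnames(tb)))
    stop("medium file must have columns: ", paste(need, collapse = ", "))
  up <- as.numeric(tb$max_uptake)
  names(up) <- tb$exchange_reaction_id
  Medium(up)
}

#' Write a medium definition to TSV
#'
#' @param medium a \linkS4class{Medium}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMedium <- function(medium, path) {
  utils::write.table(
    data.frame(exchange_reaction_id = names(medium@uptake),
               max_uptake = unname(medium@uptake)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a medium to a model
#'
#' Sets every exchange reaction's uptake-direction (lower) bound to
#' minus the medium magnitude when the exchange is present in the
#' medium, and to 0 (no uptake) otherwise.  Secretion (upper) bounds and
#' all non-exchange reactions are untouched.  Returns a new model; the
#' input is not modified.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{Medium}.
#' @return the constrained \linkS4class{MetabolicModel}.
#' @export
applyMedium <- function(model, medium) {
  ex <- exchangeReactions(model)
  bad <- setdiff(names(medium@uptake), ex)
  if (length(bad))
    stop("medium names non-exchange or unknown reaction(s): ",
         paste(bad, collapse = ", "))
  lb <- model@lb
  lb[ex] <- 0
  lb[names(medium@uptake)] <- -unname(medium@uptake)
  out <- model
  out@lb <- lb
  validObject(out)
  out
}

#' Genes behind a set of reactions
#'
#' Union of the gene leaves of the GPR rules of the named reactions.
#' Reactions with the empty rule contribute nothing.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reactionIds character vector of reaction ids.
#' @return character vector of gene ids.
#' @export
genesOfReactions <- function(model, reactionIds) {
  unknown <- setdiff(reactionIds, colnames(model@S))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  out <- unique(unlist(lapply(model@gpr[reactionIds], function(g) g@genes)))
  if (is.null(out)) character(0) else sort(out)
}

#' Extract a sub-model containing only the named reactions
#'
#' Metabolites that no longer participate in any reaction are dropped.
#' The biomass reaction id is preserved if kept, otherwise the first
#' kept reaction is (arbitrarily) designated so the object stays valid;
#' downstream code never relies on that fallback.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param keep reaction ids to retain.
#' @return a \linkS4class{MetabolicModel}.
#' @export
subsetModel <- function(model, keep) {
  unknown <- setdiff(keep, colnames(model@S))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- colnames(model@S)[colnames(model@S) %in% keep]
  S <- model@S[, keep, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  S <- S[used, , drop = FALSE]
  mets <- model@mets[model@mets$id %in% rownames(S), , drop = FALSE]
  rownames(mets) <- NULL
  biomass <- if (model@biomass %in% keep) model@biomass else keep[1]
  new("MetabolicModel", mets = mets, S = S,
      lb = model@lb[keep], ub = model@ub[keep],
      gpr = model@gpr[keep], subsystem = model@subsystem[keep],
      genes = model@genes, biomass = biomass)
}
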