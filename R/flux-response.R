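## Flux response analysis: enforce the biomass flux at increasing
## fractions of its optimum, record each reaction's flux-variability
## midpoint at every step, and correlate the midpoint series with the
## biomass series.  Reactions whose attainable flux rises with growth
## are the growth-associated candidates.

#' Scan reaction flux response to enforced biomass flux
#'
#' For each fraction f of the biomass optimum, the biomass flux is
#' pinned to f * optimum (mode \code{"fixed"}, default) or bounded below
#' by it (mode \code{"lower_bound"}); flux variability analysis over all
#' reactions yields a (min, max) range whose midpoint (min+max)/2 is
#' recorded as the reaction's mean flux at that step.  The Pearson
#' correlation between each reaction's mean-flux series and the biomass
#' flux series summarises growth coupling; a constant mean-flux series
#' has no evidence to offer and gets the sentinel r = 0.
#'
#' @param model a growing \linkS4class{MetabolicModel} (biomass optimum
#'   must be positive; gap-fill first otherwise).
#' @param fractions strictly increasing fractions in [0, 1]; default 11
#'   evenly spaced points from 0.90 to 1.00.
#' @param mode \code{"fixed"} or \code{"lower_bound"}.
#' @param reactions reactions to scan (default: all).
#' @return a \linkS4class{GrowthAssociationResult}.
#' @export
fluxResponseScan <- function(model, fractions = seq(0.90, 1.00, by = 0.01),
                             mode = c("fixed", "lower_bound"),
                             reactions = reactionIds(model)) {
  mode <- match.arg(mode)
  if (any(diff(fractions) <= 0) || any(fractions < 0) || any(fractions > 1))
    stop("fractions must be strictly increasing within [0, 1]")
  base <- fba(model, biomassReaction(model), "max")
  if (base@status != "optimal" || base@objective <= ZERO_FLUX_TOL)
    stop("no growth; gap-fill first (biomass optimum ",
         if (base@status == "optimal") base@objective else base@status, ")")
  muMax <- base@objective
  means <- matrix(NA_real_, length(reactions), length(fractions),
                  dimnames = list(reactions, NULL))
  for (k in seq_along(fractions)) {
    rng <- tryCatch(
      fva(model, objective = biomassReaction(model),
          fraction = fractions[k], reactions = reactions,
          mode = if (mode == "fixed") "fixed" else "lower_bound"),
      error = function(e)
        stop("flux-response step at fraction ", fractions[k],
             " failed: ", conditionMessage(e)))
    means[, k] <- (rng$min + rng$max) / 2
  }
  biomassFlux <- fractions * muMax
  r <- apply(means, 1, function(s) {
    if (any(!is.finite(s))) return(NA_real_)
    if (stats::sd(s) < 1e-12) return(0)
    stats::cor(s, biomassFlux)
  })
  names(r) <- reactions
  new("GrowthAssociationResult", fractions = fractions,
      biomassFlux = biomassFlux, means = means, r = r, muMax = muMax,
      mode = mode)
}

#' @export
setMethod("show", "GrowthAssociationResult", function(object) {
  cat("GrowthAssociationResult:", nrow(object@means), "reactions over",
      length(object@fractions), "fractions [",
      min(object@fractions), "-", max(object@fractions),
      "], mode =", object@mode, ", muMax =", object@muMax, "\n")
})

#' Growth-associated reactions
#'
#' Reactions whose mean-flux series correlates with the biomass series
#' above the threshold.  The inequality is strict and signed: r must
#' exceed the threshold, so anti-correlated reactions (e.g. competing
#' pathways) are not selected.
#'
#' @param result a \linkS4class{GrowthAssociationResult}.
#' @param rThreshold Pearson correlation threshold (default 0.7).
#' @return character vector of reaction ids.
#' @export
growthAssociatedReactions <- function(result, rThreshold = 0.7) {
  r <- result@r
  names(r)[!is.na(r) & r > rThreshold]
}

#' Write a flux-response result to TSV
#'
#' One row per reaction: id, Pearson r, then the mean flux at each
#' fraction; the fractions are echoed in a header comment line.
#'
#' @param result a \linkS4class{GrowthAssociationResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGrowthAssociation <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fractions: ",
                    paste(result@fractions, collapse = ","),
                    " mode: ", result@mode, " muMax: ",
                    format(result@muMax, digits = 15)), con)
  df <- data.frame(reaction = rownames(result@means),
                   r = unname(result@r), result@means,
                   check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("mean_f", result@fractions)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
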