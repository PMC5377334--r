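## Flux balance and flux variability analysis.
##
## Steady-state mass balance S v = 0 with box bounds lb <= v <= ub; all
## solves go through the package's dense simplex.  Tolerances: 1e-9 for
## constraint satisfaction inside the solver, 1e-6 when classifying a
## flux as zero (blocked reactions).

ZERO_FLUX_TOL <- 1e-6

modelLpParts <- function(model) {
  list(A = as.matrix(model@S), b = rep(0, nrow(model@S)),
       lb = unname(model@lb), ub = unname(model@ub),
       rids = colnames(model@S))
}

#' Flux balance analysis
#'
#' Optimises the flux through one reaction subject to steady-state mass
#' balance (S v = 0) and the model's flux bounds.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id to optimise; defaults to the biomass
#'   reaction.
#' @param direction \code{"max"} or \code{"min"}.
#' @return a \linkS4class{FluxResult}.  When the problem is infeasible
#'   or unbounded the status says so and no flux vector is reported.
#' @examples
#' m <- MetabolicModel(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = list(
#'     EX_A = list(stoich = c(A = -1), lb = -10, ub = 1000),
#'     R1 = list(stoich = c(A = -1, B = 1), lb = 0, ub = 1000),
#'     BIOMASS = list(stoich = c(B = -1), lb = 0, ub = 1000)),
#'   biomass = "BIOMASS")
#' fba(m)
#' @export
fba <- function(model, objective = biomassReaction(model),
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  lp <- modelLpParts(model)
  if (!objective %in% lp$rids) stop("unknown objective reaction: ", objective)
  obj <- as.numeric(lp$rids == objective)
  res <- lpSolveDense(obj, lp$A, lp$b, lp$lb, lp$ub,
                      maximize = direction == "max")
  if (res$status != "optimal")
    return(new("FluxResult", status = res$status, objective = NA_real_,
               fluxes = numeric(0)))
  fl <- res$x
  names(fl) <- lp$rids
  new("FluxResult", status = "optimal", objective = res$objective, fluxes = fl)
}

#' @export
setMethod("show", "FluxResult", function(object) {
  cat("FluxResult:", object@status)
  if (object@status == "optimal") cat(", objective =", object@objective)
  cat("\n")
})

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux for each reaction while the
#' objective reaction is held at (mode \code{"fixed"}) or above (mode
#' \code{"lower_bound"}) a fraction of its optimum.  Directions in which
#' the LP is unbounded are reported as \code{-Inf}/\code{Inf}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id constrained during the scan (default
#'   biomass).
#' @param fraction fraction of the objective optimum in [0, 1].
#' @param reactions reactions to analyse (default: all).
#' @param mode \code{"lower_bound"} (objective >= fraction * optimum,
#'   the classic FVA constraint) or \code{"fixed"} (equality).
#' @return data.frame with columns \code{reaction}, \code{min},
#'   \code{max}.
#' @export
fva <- function(model, objective = biomassReaction(model), fraction = 1,
                reactions = reactionIds(model),
                mode = c("lower_bound", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  lp <- modelLpParts(model)
  unknown <- setdiff(reactions, lp$rids)
  if (length(unknown)) stop("unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  base <- fba(model, objective, "max")
  if (base@status != "optimal")
    stop("FVA requires an optimal base solution; FBA status: ", base@status)
  objRow <- matrix(as.numeric(lp$rids == objective), nrow = 1)
  bEx <- fraction * base@objective
  sEx <- if (mode == "fixed") "=" else ">="
  res <- matrix(NA_real_, length(reactions), 2,
                dimnames = list(reactions, c("min", "max")))
  for (r in reactions) {
    obj <- as.numeric(lp$rids == r)
    for (dir in c("min", "max")) {
      s <- lpSolveDense(obj, lp$A, lp$b, lp$lb, lp$ub,
                        Aex = objRow, bex = bEx, senseEx = sEx,
                        maximize = dir == "max")
      res[r, dir] <- switch(s$status,
                            optimal = s$objective,
                            unbounded = if (dir == "max") Inf else -Inf,
                            stop("FVA ", dir, " for reaction '", r,
                                 "' failed: ", s$status))
    }
  }
  data.frame(reaction = reactions, min = unname(res[, "min"]),
             max = unname(res[, "max"]), row.names = NULL)
}

#' Blocked reactions
#'
#' Reactions whose flux is forced to zero by mass balance and bounds
#' alone (FVA with no objective constraint gives min = max = 0, within
#' the zero-flux tolerance 1e-6).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return character vector of blocked reaction ids.
#' @export
blockedReactions <- function(model) {
  lp <- modelLpParts(model)
  out <- character(0)
  for (r in lp$rids) {
    obj <- as.numeric(lp$rids == r)
    mx <- lpSolveDense(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (mx$status == "unbounded" ||
        (mx$status == "optimal" && abs(mx$objective) > ZERO_FLUX_TOL)) next
    mn <- lpSolveDense(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = FALSE)
    if (mn$status == "unbounded" ||
        (mn$status == "optimal" && abs(mn$objective) > ZERO_FLUX_TOL)) next
    if (mx$status == "optimal" && mn$status == "optimal") out <- c(out, r)
  }
  out
}
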