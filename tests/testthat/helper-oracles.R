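# Independent oracles used to freeze expected values.
#
# The LP oracle enumerates the vertices of the flux polytope
# {S v = b, lb <= v <= ub, extra rows} by activating every combination
# of inequality constraints that yields a square nonsingular system.
# For a bounded feasible polytope the optimum of any linear objective is
# attained at an enumerated vertex, so FBA optima and FVA ranges can be
# checked without touching the simplex code path.

enumVertices <- function(Aeq, beq, lb, ub, Gex = NULL, hex = NULL) {
  n <- length(lb)
  G <- rbind(diag(n), -diag(n))
  h <- c(ub, -lb)
  keep <- is.finite(h)
  G <- G[keep, , drop = FALSE]; h <- h[keep]
  if (!is.null(Gex)) { G <- rbind(G, Gex); h <- c(h, hex) }
  qrA <- qr(t(Aeq))
  r0 <- qrA$rank
  Aind <- Aeq[qrA$pivot[seq_len(r0)], , drop = FALSE]
  bind <- beq[qrA$pivot[seq_len(r0)]]
  kAct <- n - r0
  verts <- list()
  for (idx in utils::combn(nrow(G), kAct, simplify = FALSE)) {
    M <- rbind(Aind, G[idx, , drop = FALSE])
    rhs <- c(bind, h[idx])
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (max(abs(Aeq %*% v - beq)) > 1e-7) next
    if (any(G %*% v > h + 1e-7)) next
    verts[[length(verts) + 1L]] <- round(v, 9)
  }
  if (length(verts) == 0) return(matrix(numeric(0), 0, n))
  unique(do.call(rbind, verts))
}

modelVertices <- function(model, Gex = NULL, hex = NULL, AeqExtra = NULL,
                          beqExtra = NULL) {
  Aeq <- as.matrix(stoichiometry(model))
  beq <- rep(0, nrow(Aeq))
  if (!is.null(AeqExtra)) { Aeq <- rbind(Aeq, AeqExtra); beq <- c(beq, beqExtra) }
  lb <- bounds(model)$lb; ub <- bounds(model)$ub
  V <- enumVertices(Aeq, beq, lb, ub, Gex, hex)
  colnames(V) <- reactionIds(model)
  V
}

oracleFBA <- function(model, objective = biomassReaction(model),
                      direction = "max") {
  V <- modelVertices(model)
  vals <- V[, objective]
  if (direction == "max") max(vals) else min(vals)
}

oracleFVA <- function(model, objective = biomassReaction(model),
                      fraction = 1, mode = "lower_bound") {
  opt <- oracleFBA(model, objective)
  rids <- reactionIds(model)
  cvec <- as.numeric(rids == objective)
  V <- if (mode == "fixed")
    modelVertices(model, AeqExtra = matrix(cvec, 1), beqExtra = fraction * opt)
  else
    modelVertices(model, Gex = matrix(-cvec, 1), hex = -fraction * opt)
  data.frame(reaction = rids,
             min = apply(V, 2, min), max = apply(V, 2, max),
             row.names = NULL)
}

# boolean GPR oracle: textual substitution into an R logical expression
evalGprText <- function(text, present, genes) {
  e <- tolower(gsub("\\b(and)\\b", "&", gsub("\\b(or)\\b", "|", text,
                                             ignore.case = TRUE),
                    ignore.case = TRUE))
  env <- new.env()
  for (g in genes) assign(tolower(g), g %in% present, envir = env)
  isTRUE(eval(parse(text = e), envir = env))
}

# brute-force extraction oracle: enumerate reaction subsets, keep those
# admitting a certifying flux vector under the same encoding (split
# fluxes, activity >= eps per kept reaction, production slack >= eps for
# required metabolites) and passing the tasks; return the best subset by
# summed weight, ties broken toward fewer reactions
subsetFeasible <- function(model, keep, required, eps = 1e-4, bigM = 1000) {
  sub <- subsetModel(model, keep)
  if (!all(required %in% metaboliteIds(sub))) return(FALSE)
  S <- as.matrix(stoichiometry(sub))
  nk <- ncol(S); nr <- length(required)
  reqIdx <- match(required, rownames(S))
  lb <- bounds(sub)$lb; ub <- bounds(sub)$ub
  ubp <- pmin(pmax(ub, 0), bigM); ubq <- pmin(pmax(-lb, 0), bigM)
  lbp <- pmax(lb, 0)
  nv <- 2 * nk + nr
  Aeq <- cbind(S, -S, matrix(0, nrow(S), nr))
  if (nr) for (k in seq_len(nr)) Aeq[reqIdx[k], 2 * nk + k] <- -1
  Gex <- cbind(-diag(nk), -diag(nk), matrix(0, nk, nr))  # -(p+q) <= -eps
  res <- gemflux:::lpSolveDense(
    rep(0, nv), Aeq, rep(0, nrow(S)),
    lb = c(lbp, rep(0, nk), rep(eps, nr)),
    ub = c(ubp, ubq, rep(bigM, nr)),
    Aex = Gex, bex = rep(-eps, nk), senseEx = rep("<=", nk),
    maximize = TRUE)
  res$status == "optimal"
}

oracleExtraction <- function(model, weights, required = character(0),
                             tasks = list(), eps = 1e-4, bigM = 1000) {
  rids <- reactionIds(model)
  n <- length(rids)
  best <- NULL; bestObj <- -Inf; bestSize <- Inf
  for (mask in 0:(2^n - 1)) {
    keep <- rids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(keep) == 0) next
    obj <- sum(weights[keep])
    size <- length(keep)
    if (obj < bestObj - 1e-12 ||
        (obj < bestObj + 1e-12 && size >= bestSize)) next
    if (!subsetFeasible(model, keep, required, eps, bigM)) next
    if (length(tasks)) {
      chk <- checkTasks(subsetModel(model, keep), tasks,
                        missingMetabolite = "fail")
      if (!all(chk$ok)) next
    }
    best <- keep; bestObj <- obj; bestSize <- size
  }
  list(keep = best, objective = bestObj)
}

# brute-force gap-fill oracle: smallest candidate subset restoring growth
oracleGapfill <- function(model, universal, medium, minGrowth = 1e-3) {
  comb <- applyMedium(universal, medium)
  candidates <- setdiff(reactionIds(comb), reactionIds(model))
  for (k in 0:length(candidates)) {
    subs <- if (k == 0) list(integer(0))
            else utils::combn(length(candidates), k, simplify = FALSE)
    for (sub in subs) {
      keep <- union(reactionIds(model), candidates[sub])
      m <- subsetModel(comb, keep)
      m@biomass <- biomassReaction(universal)
      if (!(m@biomass %in% reactionIds(m))) next
      r <- fba(m, m@biomass, "max")
      if (r@status == "optimal" && r@objective >= minGrowth - 1e-9)
        return(list(added = candidates[sub], size = k))
    }
  }
  NULL
}
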