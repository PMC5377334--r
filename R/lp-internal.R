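## Internal LP/MILP layer.
##
## lpSolveDense() solves  optimise c'v  s.t.  Aeq v = beq,
##   Aex v (sense) bex,  lb <= v <= ub,
## by shifting/negating/splitting variables into nonnegative ones and
## handing a normalised tableau to the C++ simplex.  Infinite bounds are
## supported; unboundedness is reported, never silently truncated.

lpSolveDense <- function(obj, Aeq, beq, lb, ub,
                         Aex = NULL, bex = NULL, senseEx = NULL,
                         maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  Aeq <- if (is.null(Aeq)) matrix(0, 0, n) else as.matrix(Aeq)
  Aex <- if (is.null(Aex)) matrix(0, 0, n) else as.matrix(Aex)

  ## variable transformation: v_j = sgn_j * x_{col_j} + off_j, or v = x1 - x2
  ncols <- 0L
  colOf <- vector("list", n)
  sgn <- off <- numeric(0)
  ubRowCol <- integer(0); ubRowVal <- numeric(0)
  for (j in seq_len(n)) {
    lj <- lb[j]; uj <- ub[j]
    if (is.finite(lj)) {
      ncols <- ncols + 1L
      colOf[[j]] <- ncols; sgn <- c(sgn, 1); off <- c(off, lj)
      if (is.finite(uj)) {
        ubRowCol <- c(ubRowCol, ncols); ubRowVal <- c(ubRowVal, uj - lj)
      }
    } else if (is.finite(uj)) {
      ncols <- ncols + 1L
      colOf[[j]] <- ncols; sgn <- c(sgn, -1); off <- c(off, uj)
    } else {
      colOf[[j]] <- c(ncols + 1L, ncols + 2L)
      ncols <- ncols + 2L
      sgn <- c(sgn, 1, -1); off <- c(off, 0, 0)
    }
  }
  ## P maps x -> v
  P <- matrix(0, n, ncols)
  k <- 1L
  for (j in seq_len(n)) {
    for (cc in colOf[[j]]) { P[j, cc] <- sgn[k]; k <- k + 1L }
  }
  vOff <- numeric(n)
  k <- 1L
  for (j in seq_len(n)) { vOff[j] <- off[k]; k <- k + length(colOf[[j]]) }

  rows <- list(); rhs <- numeric(0); sense <- integer(0)
  addRow <- function(a, b, s) {
    ## normalise so rhs >= 0 (sense: 0 "<=", 1 "=", 2 ">=")
    if (b < 0) { a <- -a; b <- -b; s <- if (s == 1L) 1L else if (s == 0L) 2L else 0L }
    rows[[length(rows) + 1L]] <<- a
    rhs[length(rhs) + 1L] <<- b
    sense[length(sense) + 1L] <<- s
  }
  if (nrow(Aeq) > 0) {
    Ax <- Aeq %*% P; bx <- beq - as.numeric(Aeq %*% vOff)
    for (i in seq_len(nrow(Ax))) addRow(Ax[i, ], bx[i], 1L)
  }
  if (nrow(Aex) > 0) {
    sMap <- c("<=" = 0L, "=" = 1L, ">=" = 2L)
    Ax <- Aex %*% P; bx <- bex - as.numeric(Aex %*% vOff)
    for (i in seq_len(nrow(Ax))) addRow(Ax[i, ], bx[i], sMap[[senseEx[i]]])
  }
  for (i in seq_along(ubRowCol)) {
    a <- numeric(ncols); a[ubRowCol[i]] <- 1
    addRow(a, ubRowVal[i], 0L)
  }

  cx <- as.numeric(obj %*% P)
  cShift <- sum(obj * vOff)
  A <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, ncols)
  res <- cpp_simplex(A, rhs, sense, if (maximize) cx else -cx)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "iteration_limit")
  if (status != "optimal") return(list(status = status))
  v <- as.numeric(P %*% res$x) + vOff
  objv <- sum(obj * v)
  list(status = "optimal", objective = objv, x = v)
}

## Deterministic depth-first branch-and-bound for MILPs whose integer
## variables are binary (0/1).  Relaxations are solved by lpSolveDense.
## Branching: most fractional variable, ties to the smallest index; the
## nearer bound is explored first.  Fixed order makes results reproducible.
milpSolveBinary <- function(obj, Aeq, beq, lb, ub,
                            Aex = NULL, bex = NULL, senseEx = NULL,
                            intIdx, maximize = TRUE,
                            intTol = 1e-6, gapTol = 1e-9,
                            maxNodes = 200000L) {
  best <- NULL
  bestObj <- if (maximize) -Inf else Inf
  better <- function(a, b) if (maximize) a > b + gapTol else a < b - gapTol
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > maxNodes) stop("MILP node limit exceeded")
    rel <- lpSolveDense(obj, Aeq, beq, node$lb, node$ub,
                        Aex, bex, senseEx, maximize)
    if (rel$status == "unbounded") stop("MILP relaxation unbounded")
    if (rel$status == "iteration_limit") stop("LP iteration limit in MILP node")
    if (rel$status != "optimal") next
    if (!is.null(best) && !better(rel$objective, bestObj)) next
    yv <- rel$x[intIdx]
    frac <- abs(yv - round(yv))
    if (all(frac <= intTol)) {
      ## verify the rounding: with big-M couplings, a y parked just
      ## above 0 can pass the integrality tolerance while still letting
      ## flux through, so the rounded point must be re-proved feasible
      vlb <- node$lb; vub <- node$ub
      vlb[intIdx] <- round(yv); vub[intIdx] <- round(yv)
      ver <- lpSolveDense(obj, Aeq, beq, vlb, vub, Aex, bex, senseEx,
                          maximize)
      if (ver$status == "optimal") {
        if (is.null(best) || better(ver$objective, bestObj)) {
          best <- ver$x
          best[intIdx] <- round(yv)
          bestObj <- ver$objective
        }
        next
      }
      ## rounding infeasible: branch on the dirtiest still-free binary
      free <- intIdx[node$lb[intIdx] < node$ub[intIdx] & frac > 0]
      if (length(free) == 0) next  # relaxation itself was integral-fixed
      j <- free[which.max(frac[match(free, intIdx)])]
    } else {
      j <- intIdx[which.max(frac)]
    }
    f <- rel$x[j]
    dn <- node; dn$ub[j] <- 0
    up <- node; up$lb[j] <- 1
    ## push the less promising child first so the nearer bound pops first
    if (f - floor(f) >= 0.5) stack <- c(stack, list(dn), list(up))
    else stack <- c(stack, list(up), list(dn))
  }
  if (is.null(best)) return(list(status = "infeasible"))
  list(status = "optimal", objective = bestObj, x = best)
}
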