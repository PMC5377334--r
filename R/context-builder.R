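## Context-specific model extraction: GPR-aggregated reaction weights,
## INIT-style MILP subnetwork selection with required-production and
## metabolic-task constraints, task checking, and minimal gap-filling.

EXTRACT_EPS <- 1e-4   # minimum activity of an included reaction
EXTRACT_BIGM <- 1000  # big-M cap used when gating fluxes by inclusion

#' Reaction inclusion weights from gene scores
#'
#' Aggregates per-gene scores through each reaction's GPR rule (max over
#' OR branches, min over AND branches) and centres by -1, so that genes
#' scoring below the 30th-percentile pivot (score < 1 under the rank
#' scoring of [rankGeneScores()]) push their reactions toward exclusion.
#' Reactions without gene association get weight 0; genes missing from
#' the score table are treated as scoring the pivot value 1.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param scores a data.frame from [rankGeneScores()] (columns
#'   \code{gene}, \code{score}) or a named numeric vector.
#' @return named numeric: reaction id -> weight.
#' @export
reactionWeights <- function(model, scores) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$gene)
  w <- vapply(model@gpr, function(g) {
    if (isEmptyGpr(g)) 0 else aggregateGpr(g, scores, missing = 1) - 1
  }, numeric(1))
  names(w) <- colnames(model@S)
  w
}

#' Construct a metabolic task
#'
#' @param id,description identifiers.
#' @param inputs named nonnegative numeric: metabolite id -> maximum
#'   uptake allowed during the task.
#' @param outputs named nonnegative numeric: metabolite id -> minimum
#'   required production.
#' @param shouldFail if TRUE, the task passing is a violation (negative
#'   control for leaky networks).
#' @return a \linkS4class{MetabolicTask}.
#' @export
MetabolicTask <- function(id, description = id, inputs = numeric(0),
                          outputs, shouldFail = FALSE) {
  new("MetabolicTask", id = id, description = description,
      inputs = inputs, outputs = outputs, shouldFail = shouldFail)
}

#' Read metabolic tasks from JSON
#'
#' JSON array of objects \code{{id, description, inputs: {met: max},
#' outputs: {met: min}, should_fail}}.
#'
#' @param path file path.
#' @return list of \linkS4class{MetabolicTask}.
#' @export
readTasks <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(t) {
    MetabolicTask(id = t$id,
                  description = if (is.null(t$description)) t$id else t$description,
                  inputs = vapply(t$inputs, as.numeric, numeric(1)),
                  outputs = vapply(t$outputs, as.numeric, numeric(1)),
                  shouldFail = isTRUE(t$should_fail))
  })
}

#' Write metabolic tasks to JSON
#' @param tasks list of \linkS4class{MetabolicTask}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTasks <- function(tasks, path) {
  doc <- lapply(tasks, function(t) list(
    id = jsonlite::unbox(t@id),
    description = jsonlite::unbox(t@description),
    inputs = lapply(as.list(t@inputs), jsonlite::unbox),
    outputs = lapply(as.list(t@outputs), jsonlite::unbox),
    should_fail = jsonlite::unbox(t@shouldFail)))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

## append boundary reactions to a model without re-deriving gene sets
modelAddBoundary <- function(model, ids, mets, coefs, lb, ub) {
  add <- Matrix::sparseMatrix(i = match(mets, rownames(model@S)),
                              j = seq_along(ids), x = coefs,
                              dims = c(nrow(model@S), length(ids)),
                              dimnames = list(rownames(model@S), ids))
  out <- model
  out@S <- cbind(model@S, add)
  out@lb <- c(model@lb, stats::setNames(lb, ids))
  out@ub <- c(model@ub, stats::setNames(ub, ids))
  out@gpr <- c(model@gpr, stats::setNames(replicate(length(ids), emptyGpr()), ids))
  out@subsystem <- c(model@subsystem, stats::setNames(rep("", length(ids)), ids))
  out
}

## check one task; returns pass flag plus the reactions active in the
## certifying solutions (used for cover cuts during extraction).
## missingMetabolite = "fail" treats a metabolite absent from the model
## as unproducible/unsuppliable instead of raising an error (used when
## checking tasks on extracted submodels that may have dropped it).
taskCheckOne <- function(model, task, missingMetabolite = c("error", "fail")) {
  missingMetabolite <- match.arg(missingMetabolite)
  mets <- rownames(model@S)
  bad <- setdiff(c(names(task@inputs), names(task@outputs)), mets)
  if (length(bad)) {
    if (missingMetabolite == "error")
      stop("task '", task@id, "' references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    if (any(names(task@outputs) %in% bad))
      return(list(pass = FALSE, active = character(0)))
    task@inputs <- task@inputs[!(names(task@inputs) %in% bad)]
  }
  m <- model
  ## only the task's inputs may enter: close every exchange completely,
  ## and the biomass drain with them
  ex <- c(exchangeReactions(m), m@biomass)
  m@lb[ex] <- 0
  m@ub[ex] <- 0
  inIds <- if (length(task@inputs)) paste0("TASKIN_", names(task@inputs)) else character(0)
  outIds <- paste0("TASKOUT_", names(task@outputs))
  m <- modelAddBoundary(m, c(inIds, outIds),
                        c(names(task@inputs), names(task@outputs)),
                        c(rep(1, length(inIds)), rep(-1, length(outIds))),
                        lb = rep(0, length(inIds) + length(outIds)),
                        ub = c(unname(task@inputs),
                               rep(EXTRACT_BIGM, length(outIds))))
  active <- character(0)
  pass <- TRUE
  for (k in seq_along(outIds)) {
    res <- fba(m, objective = outIds[k], direction = "max")
    need <- unname(task@outputs[k])
    if (res@status != "optimal" || res@objective < need - 1e-9) {
      pass <- FALSE
    } else {
      fl <- res@fluxes[colnames(model@S)]
      active <- union(active, names(fl)[abs(fl) > ZERO_FLUX_TOL])
    }
  }
  list(pass = pass, active = active)
}

## reactions that can carry any flux at all in a task's environment
## (exchanges closed, task inputs/outputs open) -- everything else is
## irrelevant to that task no matter which subnetwork is selected
taskRelevantReactions <- function(model, task) {
  m <- model
  ex <- c(exchangeReactions(m), m@biomass)
  m@lb[ex] <- 0
  m@ub[ex] <- 0
  inIds <- if (length(task@inputs)) paste0("TASKIN_", names(task@inputs)) else character(0)
  outIds <- paste0("TASKOUT_", names(task@outputs))
  m <- modelAddBoundary(m, c(inIds, outIds),
                        c(names(task@inputs), names(task@outputs)),
                        c(rep(1, length(inIds)), rep(-1, length(outIds))),
                        lb = rep(0, length(inIds) + length(outIds)),
                        ub = c(unname(task@inputs),
                               rep(EXTRACT_BIGM, length(outIds))))
  rids <- colnames(model@S)
  setdiff(rids, blockedReactions(m))
}

#' Check metabolic tasks on a model
#'
#' A task passes iff, with every exchange reaction closed and only the
#' task's allowed inputs supplied, each required output can be produced
#' at at least its minimum rate (temporary demand reaction, FBA).
#' Tasks flagged \code{shouldFail} are expected to fail; such a task
#' passing is reported as a violation.  A task referencing unknown
#' metabolites is marked errored; the remaining tasks are still
#' evaluated.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tasks list of \linkS4class{MetabolicTask}.
#' @param missingMetabolite how to treat task metabolites absent from
#'   the model: \code{"error"} (default) marks the task errored;
#'   \code{"fail"} treats them as unproducible (used internally when
#'   checking extracted submodels).
#' @return data.frame with columns \code{id}, \code{pass}, \code{ok}
#'   (pass XOR shouldFail), \code{error}; the violations summary is in
#'   \code{attr(, "violations")}.
#' @export
checkTasks <- function(model, tasks,
                       missingMetabolite = c("error", "fail")) {
  missingMetabolite <- match.arg(missingMetabolite)
  rows <- lapply(tasks, function(t) {
    res <- tryCatch(taskCheckOne(model, t, missingMetabolite),
                    error = function(e) conditionMessage(e))
    if (is.character(res))
      return(data.frame(id = t@id, pass = NA, ok = FALSE, error = res))
    data.frame(id = t@id, pass = res$pass,
               ok = if (t@shouldFail) !res$pass else res$pass,
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  viol <- out$id[!out$ok]
  attr(out, "violations") <-
    if (length(viol)) paste("violated task(s):", paste(viol, collapse = ", "))
    else "none"
  out
}

## MILP parts shared by extraction (variables p, q, y, s)
extractionMilp <- function(model, weights, required, eps, bigM) {
  n <- ncol(model@S)
  rids <- colnames(model@S)
  m <- nrow(model@S)
  reqIdx <- match(required, rownames(model@S))
  nReq <- length(required)
  ## columns: p (1..n), q (n+1..2n), y (2n+1..3n), s (3n+1..3n+nReq)
  nv <- 3 * n + nReq
  ubp <- pmin(pmax(model@ub, 0), bigM)
  ubq <- pmin(pmax(-model@lb, 0), bigM)
  lbp <- pmax(model@lb, 0)  # forced forward flux when lb > 0

  S <- as.matrix(model@S)
  Aeq <- matrix(0, m, nv)
  Aeq[, 1:n] <- S
  Aeq[, (n + 1):(2 * n)] <- -S
  if (nReq) for (k in seq_len(nReq)) Aeq[reqIdx[k], 3 * n + k] <- -1
  beq <- rep(0, m)

  rowsA <- list(); rhs <- numeric(0); sns <- character(0)
  addRow <- function(cols, vals, b, s) {
    a <- numeric(nv); a[cols] <- vals
    rowsA[[length(rowsA) + 1L]] <<- a
    rhs[length(rhs) + 1L] <<- b
    sns[length(sns) + 1L] <<- s
  }
  for (j in seq_len(n)) {
    addRow(c(j, 2 * n + j), c(1, -ubp[j]), 0, "<=")          # p <= ubp*y
    addRow(c(n + j, 2 * n + j), c(1, -ubq[j]), 0, "<=")      # q <= ubq*y
    addRow(c(j, n + j, 2 * n + j), c(1, 1, -eps), 0, ">=")   # p+q >= eps*y
    if (lbp[j] > 0)
      addRow(c(j, 2 * n + j), c(1, -lbp[j]), 0, ">=")        # p >= lb*y
  }
  ## a tiny per-inclusion penalty selects the smallest network among
  ## weight-optimal ones, making ties deterministic; the reported
  ## objective is the pure weight sum
  tieEps <- 1e-6
  list(obj = c(rep(0, 2 * n), unname(weights[rids]) - tieEps, rep(0, nReq)),
       Aeq = Aeq, beq = beq,
       lb = c(rep(0, 2 * n + n), rep(eps, nReq)),
       ub = c(ubp, ubq, rep(1, n), rep(bigM, nReq)),
       Aex = if (length(rowsA)) do.call(rbind, rowsA) else NULL,
       bex = rhs, senseEx = sns,
       intIdx = (2 * n + 1):(3 * n), n = n, rids = rids)
}

#' Extract a context-specific model by mixed-integer programming
#'
#' Selects the reaction subset maximising the summed inclusion weights
#' subject to: a certifying steady-state flux vector in which every
#' included reaction carries activity of at least \code{eps} (reversible
#' reactions are split into forward/backward nonnegative parts) and no
#' excluded reaction carries any; a production slack of at least
#' \code{eps} for every required metabolite; and, via iterative cut
#' generation, all metabolic tasks behaving as demanded (must-pass tasks
#' pass, should-fail tasks fail) on the extracted model.
#'
#' @param universal the universal \linkS4class{MetabolicModel}.
#' @param weights named numeric inclusion weights (see
#'   [reactionWeights()]); must cover all reactions.
#' @param requiredProduction metabolite ids that the extracted model
#'   must be able to produce.
#' @param tasks list of \linkS4class{MetabolicTask} (may be empty).
#' @param medium optional \linkS4class{Medium} applied before
#'   extraction.
#' @param eps minimum flux activity for included reactions (default 1e-4).
#' @param bigM big-M flux cap (default 1000).
#' @param maxIter maximum task-cut iterations (default 20).
#' @return an \linkS4class{ExtractionResult}.
#' @export
extractContextModel <- function(universal, weights,
                                requiredProduction = character(0),
                                tasks = list(), medium = NULL,
                                eps = EXTRACT_EPS, bigM = EXTRACT_BIGM,
                                maxIter = 20L) {
  model <- if (is.null(medium)) universal else applyMedium(universal, medium)
  rids <- colnames(model@S)
  if (!all(rids %in% names(weights)))
    stop("weights must be defined for every reaction")
  bad <- setdiff(requiredProduction, rownames(model@S))
  if (length(bad))
    stop("required metabolite(s) not in the model: ",
         paste(bad, collapse = ", "))

  parts <- extractionMilp(model, weights, requiredProduction, eps, bigM)
  cuts <- list()
  relevantCache <- list()
  for (iter in seq_len(maxIter)) {
    Aex <- parts$Aex; bex <- parts$bex; sns <- parts$senseEx
    for (ct in cuts) {
      Aex <- rbind(Aex, ct$a); bex <- c(bex, ct$b); sns <- c(sns, ct$s)
    }
    sol <- milpSolveBinary(parts$obj, parts$Aeq, parts$beq, parts$lb,
                           parts$ub, Aex, bex, sns,
                           intIdx = parts$intIdx, maximize = TRUE)
    if (sol$status != "optimal") {
      stop(if (length(cuts) == 0)
             "extraction MILP infeasible: required-metabolite production cannot be satisfied"
           else
             "extraction MILP infeasible: metabolic-task constraints cannot be satisfied")
    }
    n <- parts$n
    y <- sol$x[parts$intIdx] > 0.5
    names(y) <- rids
    kept <- rids[y]
    extracted <- subsetModel(model, kept)
    if (length(tasks) == 0) {
      return(buildExtraction(model, extracted, sol, y, weights, parts))
    }
    chk <- checkTasks(extracted, tasks, missingMetabolite = "fail")
    if (all(chk$ok)) {
      return(buildExtraction(model, extracted, sol, y, weights, parts))
    }
    ## cover cuts: a failing must-pass task needs at least one of the
    ## currently excluded reactions that can carry flux in that task's
    ## environment (task feasibility is monotone in the reaction set,
    ## so the restriction to task-relevant reactions is valid); a
    ## passing should-fail task must lose at least one of the reactions
    ## active in its certificate
    for (k in which(!chk$ok)) {
      t <- tasks[[k]]
      if (!isTRUE(t@shouldFail)) {
        if (is.null(relevantCache[[t@id]]))
          relevantCache[[t@id]] <- taskRelevantReactions(model, t)
        excl <- which(!y & rids %in% relevantCache[[t@id]])
        if (length(excl) == 0)
          stop("extraction MILP infeasible: task '", t@id,
               "' fails even with every relevant reaction included")
        a <- numeric(length(parts$obj))
        a[2 * n + excl] <- 1
        cuts[[length(cuts) + 1L]] <- list(a = a, b = 1, s = ">=")
      } else {
        act <- taskCheckOne(extracted, t, missingMetabolite = "fail")$active
        act <- intersect(act, kept)
        if (length(act) == 0) act <- kept
        a <- numeric(length(parts$obj))
        a[2 * n + match(act, rids)] <- 1
        cuts[[length(cuts) + 1L]] <- list(a = a, b = length(act) - 1, s = "<=")
      }
    }
  }
  stop("extraction did not converge within ", maxIter, " task-cut iterations")
}

buildExtraction <- function(model, extracted, sol, kept, weights, parts) {
  n <- parts$n
  v <- sol$x[1:n] - sol$x[(n + 1):(2 * n)]
  names(v) <- parts$rids
  new("ExtractionResult", model = extracted,
      objective = sum(weights[parts$rids][kept]),
      weights = weights[parts$rids], kept = kept, fluxes = v,
      status = "optimal")
}

#' @export
setMethod("show", "ExtractionResult", function(object) {
  cat("ExtractionResult:", sum(object@kept), "of", length(object@kept),
      "reactions kept; objective =", object@objective, "\n")
})

#' Minimal gap-filling to restore growth
#'
#' Finds a minimum-cardinality set of reactions from the universal model
#' whose addition lets the model reach at least \code{minGrowth} biomass
#' flux on the given medium (GrowMatch-style).  Zero additions are
#' returned when the model already grows.
#'
#' @param model the (possibly non-growing) \linkS4class{MetabolicModel}.
#' @param universal the universal model; its reaction set must contain
#'   the model's.
#' @param medium optional \linkS4class{Medium} applied to the combined
#'   network.
#' @param minGrowth minimum biomass flux demanded (default 1e-3).
#' @param bigM big-M flux cap for unbounded candidate reactions.
#' @return a \linkS4class{GapfillResult}.
#' @export
gapfillGrowth <- function(model, universal, medium = NULL,
                          minGrowth = 1e-3, bigM = EXTRACT_BIGM) {
  if (!all(colnames(model@S) %in% colnames(universal@S)))
    stop("universal model must contain every model reaction")
  comb <- universal
  if (!is.null(medium)) comb <- applyMedium(comb, medium)
  candidates <- setdiff(colnames(comb@S), colnames(model@S))

  full <- fba(comb, objective = comb@biomass, direction = "max")
  if (full@status != "optimal" || full@objective < minGrowth - 1e-9) {
    dead <- limitingDeadEnds(comb)
    stop("gap-filling infeasible: even the universal network cannot reach ",
         minGrowth, " biomass flux; limiting dead-end metabolite(s): ",
         if (length(dead)) paste(dead, collapse = ", ") else "<none found>")
  }
  n <- ncol(comb@S)
  rids <- colnames(comb@S)
  candIdx <- match(candidates, rids)
  nc <- length(candIdx)
  lb <- unname(comb@lb); ub <- unname(comb@ub)
  lb[rids == comb@biomass] <- minGrowth
  stopifnot(comb@biomass %in% rids)
  if (nc == 0) {
    res <- fba(comb, comb@biomass, "max")
    return(new("GapfillResult", added = character(0),
               growth = res@objective, status = "optimal"))
  }
  ## vars: v (1..n), y (n+1..n+nc); v_c in [lb_c*y, ub_c*y]
  nv <- n + nc
  Aeq <- cbind(as.matrix(comb@S), matrix(0, nrow(comb@S), nc))
  rowsA <- list(); rhs <- numeric(0); sns <- character(0)
  for (k in seq_len(nc)) {
    j <- candIdx[k]
    a <- numeric(nv); a[j] <- 1; a[n + k] <- -min(max(ub[j], 0), bigM)
    rowsA[[length(rowsA) + 1L]] <- a; rhs <- c(rhs, 0); sns <- c(sns, "<=")
    a <- numeric(nv); a[j] <- 1; a[n + k] <- -max(min(lb[j], 0), -bigM)
    rowsA[[length(rowsA) + 1L]] <- a; rhs <- c(rhs, 0); sns <- c(sns, ">=")
  }
  obj <- c(rep(0, n), rep(1, nc))
  sol <- milpSolveBinary(obj, Aeq, rep(0, nrow(Aeq)),
                         lb = c(lb, rep(0, nc)), ub = c(ub, rep(1, nc)),
                         Aex = do.call(rbind, rowsA), bex = rhs,
                         senseEx = sns, intIdx = (n + 1):(n + nc),
                         maximize = FALSE)
  if (sol$status != "optimal")
    stop("gap-filling MILP infeasible at minGrowth = ", minGrowth)
  added <- candidates[sol$x[(n + 1):(n + nc)] > 0.5]
  filled <- subsetModel(comb, union(colnames(model@S), added))
  filled@biomass <- comb@biomass
  ## growth is re-measured on the filled model under the medium
  res <- fba(filled, comb@biomass, "max")
  new("GapfillResult", added = added, growth = res@objective,
      status = "optimal")
}

## metabolites consumed by the biomass reaction that the network cannot
## produce at all (diagnostic for infeasible gap-filling)
limitingDeadEnds <- function(model) {
  st <- model@S[, model@biomass]
  subs <- rownames(model@S)[st < 0]
  dead <- character(0)
  for (m in subs) {
    test <- modelAddBoundary(model, "DEADEND_PROBE", m, -1, 0, EXTRACT_BIGM)
    res <- fba(test, "DEADEND_PROBE", "max")
    if (res@status != "optimal" || res@objective < ZERO_FLUX_TOL)
      dead <- c(dead, m)
  }
  dead
}

#' @export
setMethod("show", "GapfillResult", function(object) {
  cat("GapfillResult:", length(object@added), "reaction(s) added; growth =",
      object@growth, "\n")
})
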