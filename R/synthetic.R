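## Synthetic-data generator.  Produces a coherent bundle -- toy
## metabolic model, duplicate-sample expression, metabolome with
## detection dropouts, regulatory network -- with planted ground truth,
## so that every pipeline stage can be validated end to end without any
## external download.  Every output is a pure function of the spec
## (seed included); generators save and restore the caller's RNG state.

#' Construct a synthetic-data specification
#'
#' The defaults define the emulated study conditions: duplicate
#' profiles per cell type, planted 2-fold expression effects under
#' multiplicative lognormal noise (sdlog 0.1), a linear growth-coupled
#' pathway plus flux-feasible but growth-decoupled decoy reactions, and
#' a regulatory network in which one master TF targets exactly the
#' coupled-pathway genes.
#'
#' @param seed integer seed; fully determines every generated output.
#' @param nCoupled coupled-pathway length in reactions (default 6).
#' @param nDecoy number of decoy reactions (default 4).
#' @param nGenes gene pool size (default 240).
#' @param nPlantedUp planted up-regulated genes, includes the coupled
#'   genes (default 20).
#' @param nPlantedDown planted down-regulated genes (default 10).
#' @param effectSize planted fold change (default 2).
#' @param noiseSd lognormal noise scale, sdlog (default 0.1).
#' @param replicates samples per group (default 2).
#' @param nTfs number of TFs, one master plus decoys (default 8).
#' @param masterCoverage fraction of coupled genes targeted by the
#'   master TF (default 1).
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed = 1L, nCoupled = 6L, nDecoy = 4L,
                          nGenes = 240L, nPlantedUp = 20L,
                          nPlantedDown = 10L, effectSize = 2,
                          noiseSd = 0.1, replicates = 2L, nTfs = 8L,
                          masterCoverage = 1) {
  new("SyntheticSpec", seed = as.integer(seed),
      nCoupled = as.integer(nCoupled), nDecoy = as.integer(nDecoy),
      nGenes = as.integer(nGenes), nPlantedUp = as.integer(nPlantedUp),
      nPlantedDown = as.integer(nPlantedDown),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      replicates = as.integer(replicates), nTfs = as.integer(nTfs),
      masterCoverage = as.numeric(masterCoverage))
}

## run code under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  })
  set.seed(seed %% 2100000000L)
  force(code)
}

## deterministic gene pool and planted-set assignment shared by the
## generators; coupled genes are the head of the planted-up sample
syntheticGenePlan <- function(spec) {
  withSeed(spec@seed, {
    pool <- sprintf("g%04d", seq_len(spec@nGenes))
    plantedUp <- sample(pool, spec@nPlantedUp)
    rest <- setdiff(pool, plantedUp)
    plantedDown <- if (spec@nPlantedDown > 0) sample(rest, spec@nPlantedDown)
                   else character(0)
    nulls <- setdiff(rest, plantedDown)
    decoyGenes <- sample(nulls, spec@nDecoy)
    list(pool = pool, plantedUp = plantedUp, plantedDown = plantedDown,
         nulls = nulls, coupledGenes = plantedUp[seq_len(spec@nCoupled)],
         decoyGenes = decoyGenes)
  })
}

#' Generate the toy metabolic model
#'
#' One linear biomass pathway (glucose-like uptake, chain of conversions
#' into a biomass precursor drained by the biomass reaction) whose flux
#' scales with growth, plus decoy reactions that can carry flux bounded
#' independently of biomass (own substrate uptake, own sink, capped
#' rate).  Chain reactions carry GPRs referencing the planted-up genes
#' (single genes alternating with isoenzyme ORs); decoys carry decoy
#' genes; exchanges and biomass have no gene association.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{model}, \code{medium} (uptake 10 for
#'   the pathway substrate, 5 for decoy substrates), \code{tasks}, and
#'   \code{truth} (coupled/decoy reaction ids, gene sets, master TF id).
#' @export
generateToyModel <- function(spec) {
  plan <- syntheticGenePlan(spec)
  nC <- spec@nCoupled
  chainMets <- paste0("M", 0:nC)
  mets <- data.frame(id = chainMets, name = chainMets, compartment = "c")
  reactions <- list()
  reactions$EX_M0 <- list(stoich = c(M0 = -1), lb = -1000, ub = 1000,
                          subsystem = "exchange")
  for (i in seq_len(nC)) {
    st <- stats::setNames(c(-1, 1), c(chainMets[i], chainMets[i + 1]))
    ## alternate single-gene and isoenzyme-OR rules over planted-up genes
    g <- plan$coupledGenes[i]
    gpr <- if (i %% 2 == 0 && spec@nPlantedUp > nC) {
      extra <- plan$plantedUp[nC + 1 + (i %% (spec@nPlantedUp - nC))]
      paste(g, "or", extra)
    } else g
    reactions[[paste0("R_C", i)]] <- list(stoich = st, lb = 0, ub = 1000,
                                          gpr = gpr,
                                          subsystem = "coupled_pathway")
  }
  reactions$BIOMASS <- list(
    stoich = stats::setNames(-1, chainMets[nC + 1]),
    lb = 0, ub = 1000, subsystem = "biomass")
  for (i in seq_len(spec@nDecoy)) {
    w <- paste0("W", i); z <- paste0("Z", i)
    mets <- rbind(mets, data.frame(id = c(w, z), name = c(w, z),
                                   compartment = "c"))
    reactions[[paste0("EX_W", i)]] <- list(
      stoich = stats::setNames(-1, w), lb = -1000, ub = 1000,
      subsystem = "exchange")
    reactions[[paste0("R_D", i)]] <- list(
      stoich = stats::setNames(c(-1, 1), c(w, z)), lb = 0, ub = 5,
      gpr = plan$decoyGenes[i], subsystem = "decoy")
    reactions[[paste0("EX_Z", i)]] <- list(
      stoich = stats::setNames(-1, z), lb = 0, ub = 1000,
      subsystem = "exchange")
  }
  model <- MetabolicModel(mets, reactions, biomass = "BIOMASS",
                          genes = plan$pool)
  medium <- Medium(stats::setNames(
    c(10, rep(5, spec@nDecoy)),
    c("EX_M0", paste0("EX_W", seq_len(spec@nDecoy)))))
  tasks <- c(
    lapply(seq_len(nC), function(i) MetabolicTask(
      id = paste0("produce_M", i),
      description = paste0("produce chain intermediate M", i,
                           " from the pathway substrate"),
      inputs = c(M0 = 10),
      outputs = stats::setNames(0.1, paste0("M", i)))),
    list(MetabolicTask(id = "decoy_conversion",
                       description = "convert the first decoy substrate",
                       inputs = c(W1 = 5),
                       outputs = c(Z1 = 0.1)),
         MetabolicTask(id = "no_free_lunch",
                       description = "biomass precursor from nothing must fail",
                       inputs = numeric(0),
                       outputs = stats::setNames(0.1, chainMets[nC + 1]),
                       shouldFail = TRUE)))
  truth <- list(coupledReactions = c(paste0("R_C", seq_len(nC)), "BIOMASS"),
                decoyReactions = paste0("R_D", seq_len(spec@nDecoy)),
                plantedUp = plan$plantedUp, plantedDown = plan$plantedDown,
                coupledGenes = plan$coupledGenes,
                decoyGenes = plan$decoyGenes,
                masterTf = "TF_master")
  list(model = model, medium = medium, tasks = tasks, truth = truth)
}

#' Generate synthetic expression data
#'
#' Lognormal baseline intensities; planted up (down) genes multiplied
#' (divided) by the effect size in group A; multiplicative lognormal
#' noise in every cell.  Groups are labelled \code{CD133pos} (A) and
#' \code{CD133neg} (B) with the spec's replicate count.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param genePool character vector of gene ids.
#' @param plantedUp,plantedDown planted gene sets (subsets of the pool).
#' @return a \code{SummarizedExperiment} (see [ExpressionTable()]).
#' @export
generateExpression <- function(spec, genePool = NULL, plantedUp = NULL,
                               plantedDown = NULL) {
  if (is.null(genePool)) {
    plan <- syntheticGenePlan(spec)
    genePool <- plan$pool; plantedUp <- plan$plantedUp
    plantedDown <- plan$plantedDown
  }
  stopifnot(all(plantedUp %in% genePool), all(plantedDown %in% genePool))
  withSeed(spec@seed + 1L, {
    n <- length(genePool)
    reps <- spec@replicates
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    meanA <- base
    meanA[genePool %in% plantedUp] <- meanA[genePool %in% plantedUp] * spec@effectSize
    meanA[genePool %in% plantedDown] <- meanA[genePool %in% plantedDown] / spec@effectSize
    noise <- function() exp(stats::rnorm(n, 0, spec@noiseSd))
    A <- vapply(seq_len(reps), function(i) meanA * noise(), numeric(n))
    B <- vapply(seq_len(reps), function(i) base * noise(), numeric(n))
    mat <- cbind(A, B)
    rownames(mat) <- genePool
    colnames(mat) <- c(paste0("CD133pos_", seq_len(reps)),
                       paste0("CD133neg_", seq_len(reps)))
    ExpressionTable(mat, rep(c("CD133pos", "CD133neg"), each = reps))
  })
}

#' Generate a synthetic metabolome table
#'
#' Concentrations realise the planted fold changes (group A over B);
#' the dropout map plants detection categories deterministically.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param foldChanges named numeric: metabolite name -> planted fold
#'   change (these metabolites are detected in both types).
#' @param dropouts named character: metabolite name -> one of
#'   \code{"A_only"}, \code{"B_only"}, \code{"neither"},
#'   \code{"irreproducible"}.
#' @param putative names of metabolites to label as putative (relative
#'   areas); the rest are standard.
#' @return a \linkS4class{MetabolomeTable} with cell types
#'   \code{CD133pos} / \code{CD133neg}.
#' @export
generateMetabolome <- function(spec, foldChanges, dropouts = character(0),
                               putative = character(0)) {
  withSeed(spec@seed + 2L, {
    reps <- spec@replicates
    nms <- c(names(foldChanges), names(dropouts))
    if (anyDuplicated(nms)) stop("fold-change and dropout maps overlap")
    n <- length(nms)
    base <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.5)
    names(base) <- nms
    noise <- function(k) exp(stats::rnorm(k, 0, spec@noiseSd))
    conc <- matrix(NA_real_, n, 2 * reps,
                   dimnames = list(nms, c(paste0("CD133pos_", seq_len(reps)),
                                          paste0("CD133neg_", seq_len(reps)))))
    A <- seq_len(reps); B <- reps + seq_len(reps)
    for (m in names(foldChanges)) {
      conc[m, A] <- base[m] * foldChanges[[m]] * noise(reps)
      conc[m, B] <- base[m] * noise(reps)
    }
    for (m in names(dropouts)) {
      vals <- c(base[m] * noise(reps), base[m] * noise(reps))
      conc[m, ] <- switch(dropouts[[m]],
        A_only = { vals[B] <- NA; vals },
        B_only = { vals[A] <- NA; vals },
        neither = rep(NA_real_, 2 * reps),
        irreproducible = { vals[c(A[1], B)] <- NA; vals },
        stop("unknown dropout category: ", dropouts[[m]]))
    }
    cls <- ifelse(nms %in% putative, "putative", "standard")
    MetabolomeTable(conc, stats::setNames(cls, nms))
  })
}

#' Generate a synthetic regulatory network
#'
#' One master TF targets \code{masterCoverage} of the coupled-pathway
#' genes; the remaining TFs are decoys targeting only decoy genes.  All
#' edges carry the High confidence / Experimental evidence labels.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param coupledGenes,decoyGenes disjoint gene sets.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
generateRegulatoryNetwork <- function(spec, coupledGenes = NULL,
                                      decoyGenes = NULL) {
  if (is.null(coupledGenes)) {
    plan <- syntheticGenePlan(spec)
    coupledGenes <- plan$coupledGenes; decoyGenes <- plan$decoyGenes
  }
  if (length(intersect(coupledGenes, decoyGenes)))
    stop("coupled and decoy gene sets must be disjoint")
  withSeed(spec@seed + 3L, {
    k <- max(1L, ceiling(spec@masterCoverage * length(coupledGenes)))
    masterTargets <- sort(coupledGenes)[seq_len(k)]
    edges <- data.frame(TF = "TF_master", target = masterTargets,
                        confidence = "High", evidence = "Experimental")
    for (i in seq_len(spec@nTfs - 1L)) {
      tg <- sample(decoyGenes, max(1L, sample(length(decoyGenes), 1)))
      edges <- rbind(edges, data.frame(
        TF = sprintf("TF_d%02d", i), target = tg,
        confidence = "High", evidence = "Experimental"))
    }
    RegulatoryNetwork(edges)
  })
}

#' Generate the full synthetic bundle
#'
#' Composes the toy model, medium, task list, expression table,
#' metabolome (planted 3-fold and null fold changes plus one dropout of
#' each category), synonym table (metabolome names -> chain metabolite
#' ids) and regulatory network, together with the planted ground truth.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return named list: \code{spec}, \code{model}, \code{medium},
#'   \code{tasks}, \code{expression}, \code{metabolome},
#'   \code{synonyms}, \code{network}, \code{truth}.
#' @export
generateBundle <- function(spec) {
  toy <- generateToyModel(spec)
  plan <- syntheticGenePlan(spec)
  expr <- generateExpression(spec, plan$pool, plan$plantedUp,
                             plan$plantedDown)
  nC <- spec@nCoupled
  fcs <- stats::setNames(rep(1, nC), paste0("met_M", seq_len(nC)))
  fcs[1] <- 3.0                      # planted accumulation in group A
  if (nC >= 3) fcs[3] <- 2.0
  drops <- c(met_dropA = "A_only", met_dropB = "B_only",
             met_none = "neither", met_irre = "irreproducible")
  metab <- generateMetabolome(spec, fcs, drops,
                              putative = paste0("met_M", nC))
  synonyms <- stats::setNames(paste0("M", seq_len(nC)),
                              paste0("met_M", seq_len(nC)))
  network <- generateRegulatoryNetwork(spec, plan$coupledGenes,
                                       plan$decoyGenes)
  list(spec = spec, model = toy$model, medium = toy$medium,
       tasks = toy$tasks, expression = expr, metabolome = metab,
       synonyms = synonyms, network = network, truth = toy$truth)
}

#' Write a synthetic bundle to a directory
#'
#' Writes the model (JSON and SBML), medium, tasks, expression and
#' group tables, metabolome, synonyms, network, ground truth (JSON) and
#' a ready-to-run pipeline configuration (YAML).
#'
#' @param bundle list from [generateBundle()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeModel(bundle$model, fp("model.json"), "json")
  writeModel(bundle$model, fp("model.xml"), "sbml")
  writeMedium(bundle$medium, fp("medium.tsv"))
  writeTasks(bundle$tasks, fp("tasks.json"))
  mat <- exprMatrix(bundle$expression)
  utils::write.table(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     fp("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(mat),
                                group = exprGroups(bundle$expression)),
                     fp("groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeMetabolome(bundle$metabolome, fp("metabolome.tsv"))
  utils::write.table(data.frame(metabolite = names(bundle$synonyms),
                                model_id = unname(bundle$synonyms)),
                     fp("synonyms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$network@edges, fp("network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  cfg <- list(
    paths = list(model = "model.json", expression = "expression.tsv",
                 groups = "groups.tsv", metabolome = "metabolome.tsv",
                 synonyms = "synonyms.tsv", network = "network.tsv",
                 medium = "medium.tsv", tasks = "tasks.json"),
    groups = list(target = "CD133pos", reference = "CD133neg"),
    thresholds = list(p = 0.05, fc = 1.5, rank_fraction = 0.3, r = 0.7),
    fractions = list(start = 0.90, stop = 1.00, steps = 11),
    scan_mode = "fixed",
    extraction = list(eps = 1e-4, big_m = 1000),
    confidence_filter = "High",
    min_growth = 1e-3)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}
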