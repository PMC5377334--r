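## End-to-end orchestration: differential expression -> rank scoring ->
## per-replicate context extraction -> gap-fill -> flux-response scan ->
## TF ranking, driven by a YAML configuration, with stage outputs
## cached to files so a rerun with unchanged inputs can resume.

pipelineConfigSchema <- list(
  paths = c("model", "expression", "groups", "metabolome", "synonyms",
            "network", "medium", "tasks"),
  groups = c("target", "reference"),
  thresholds = c("p", "fc", "rank_fraction", "r"),
  fractions = c("start", "stop", "steps"),
  scan_mode = NULL, extraction = c("eps", "big_m"),
  confidence_filter = NULL, min_growth = NULL)

#' Read and validate a pipeline configuration
#'
#' YAML file with sections \code{paths} (model, expression, groups,
#' metabolome, synonyms, network, medium, tasks), \code{groups}
#' (target, reference), \code{thresholds} (p, fc, rank_fraction, r),
#' \code{fractions} (start, stop, steps), \code{scan_mode},
#' \code{extraction} (eps, big_m), \code{confidence_filter},
#' \code{min_growth}.  Unknown keys are a configuration error; relative
#' paths resolve against the config file's directory; all referenced
#' paths must exist (pre-flight check, before any computation).
#'
#' @param path configuration file path.
#' @return validated configuration list (paths made absolute).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(pipelineConfigSchema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(pipelineConfigSchema)) {
    allowed <- pipelineConfigSchema[[sec]]
    if (is.null(allowed)) next
    unknown <- setdiff(names(cfg[[sec]]), allowed)
    if (length(unknown))
      stop("unknown config key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  defaults <- list(
    groups = list(target = "CD133pos", reference = "CD133neg"),
    thresholds = list(p = 0.05, fc = 1.5, rank_fraction = 0.3, r = 0.7),
    fractions = list(start = 0.90, stop = 1.00, steps = 11),
    scan_mode = "fixed", extraction = list(eps = 1e-4, big_m = 1000),
    confidence_filter = "High", min_growth = 1e-3)
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
    else if (is.list(defaults[[sec]]))
      for (k in names(defaults[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- defaults[[sec]][[k]]
  }
  th <- cfg$thresholds
  if (th$p <= 0 || th$p >= 1) stop("config: p threshold must be in (0, 1)")
  if (th$fc <= 1) stop("config: fc threshold must exceed 1")
  if (th$rank_fraction <= 0 || th$rank_fraction > 1)
    stop("config: rank_fraction must be in (0, 1]")
  if (th$r < -1 || th$r >= 1) stop("config: r threshold must be in [-1, 1)")
  fr <- cfg$fractions
  if (fr$start < 0 || fr$stop > 1 || fr$start >= fr$stop || fr$steps < 2)
    stop("config: fractions must satisfy 0 <= start < stop <= 1, steps >= 2")
  if (!cfg$scan_mode %in% c("fixed", "lower_bound"))
    stop("config: scan_mode must be 'fixed' or 'lower_bound'")
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    ap <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    if (!file.exists(ap)) stop("config path does not exist: ", p)
    ap
  })
  need <- pipelineConfigSchema$paths
  miss <- setdiff(need, names(cfg$paths))
  if (length(miss))
    stop("config missing path(s): ", paste(miss, collapse = ", "))
  cfg
}

## medium restricted to exchanges present in a (sub)model
mediumForModel <- function(medium, model) {
  keep <- names(medium@uptake) %in% exchangeReactions(model)
  Medium(medium@uptake[keep])
}

pipelineLog <- function(...) message("[gemflux] ", ...)

#' Run the full analysis pipeline
#'
#' Stages, in order: differential expression (raw-p Student's t plus
#' fold-change gate), per-replicate rank scoring of the model genes in
#' the target group, context-specific model extraction per replicate
#' (required metabolite production from the metabolome, task
#' constraints, medium), gap-filling to the configured minimum growth,
#' flux-response scan with growth-associated reaction selection, and
#' transcription-factor ranking over the union of growth-associated
#' genes.  Stage outputs are written to \code{outdir}; with
#' \code{resume = TRUE}, stages whose output files already exist are
#' loaded instead of recomputed.  Identical configuration and inputs
#' give identical outputs.
#'
#' @param config path to a YAML configuration (see
#'   [readPipelineConfig()]) or an already-validated config list.
#' @param outdir output directory.
#' @param resume reuse existing stage outputs (default FALSE).
#' @param quiet suppress progress messages.
#' @return the pipeline report: list with elements \code{de},
#'   \code{scores}, \code{extraction}, \code{gapfill},
#'   \code{growthAssociation}, \code{growthReactions},
#'   \code{growthGenes}, \code{tfRanking}, \code{provenance}.
#' @export
runPipeline <- function(config, outdir, resume = FALSE, quiet = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- if (quiet) function(...) invisible() else pipelineLog

  model <- readModel(cfg$paths$model)
  expr <- readExpression(cfg$paths$expression, cfg$paths$groups)
  metab <- readMetabolome(cfg$paths$metabolome)
  synonyms <- readSynonyms(cfg$paths$synonyms)
  medium <- readMedium(cfg$paths$medium)
  tasks <- readTasks(cfg$paths$tasks)
  network <- loadRegulatoryNetwork(cfg$paths$network,
                                   confidenceFilter = cfg$confidence_filter)
  target <- cfg$groups$target; reference <- cfg$groups$reference

  ## stage 1: differential expression
  deFile <- file.path(outdir, "de.tsv")
  if (resume && file.exists(deFile)) {
    say("resume: differential expression")
    de <- utils::read.delim(deFile, stringsAsFactors = FALSE)
  } else {
    say("differential expression (", target, " vs ", reference, ")")
    de <- differentialExpression(expr, target, reference,
                                 pThreshold = cfg$thresholds$p,
                                 fcThreshold = cfg$thresholds$fc)
    utils::write.table(de, deFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## stage 2: per-replicate rank scores over the model's genes
  mat <- exprMatrix(expr)
  targetSamples <- colnames(mat)[exprGroups(expr) == target]
  modelGenes <- intersect(rownames(mat), geneIds(model))
  if (length(modelGenes) == 0) stop("no model gene appears in the expression table")
  scores <- list()
  for (s in targetSamples) {
    f <- file.path(outdir, paste0("scores_", s, ".tsv"))
    if (resume && file.exists(f)) {
      scores[[s]] <- utils::read.delim(f, stringsAsFactors = FALSE)
    } else {
      scores[[s]] <- rankGeneScores(stats::setNames(mat[modelGenes, s],
                                                    modelGenes),
                                    fraction = cfg$thresholds$rank_fraction)
      utils::write.table(scores[[s]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  ## stage 3 + 4: extraction and gap-fill per replicate
  required <- productionTargets(metab, model, synonyms, type = target)$matched
  extraction <- list(); gapfill <- list()
  for (s in targetSamples) {
    exFile <- file.path(outdir, paste0("extracted_", s, ".json"))
    gfFile <- file.path(outdir, paste0("gapfill_", s, ".json"))
    if (resume && file.exists(exFile) && file.exists(gfFile)) {
      say("resume: extraction/gap-fill for ", s)
      gf <- jsonlite::read_json(gfFile, simplifyVector = TRUE)
      extraction[[s]] <- list(model = readModel(exFile, "json"),
                              kept = NULL, objective = gf$objective)
      gapfill[[s]] <- list(added = as.character(gf$added),
                           growth = gf$growth)
      next
    }
    say("extracting context model for ", s)
    w <- reactionWeights(model, scores[[s]])
    ex <- extractContextModel(model, w, requiredProduction = required,
                              tasks = tasks, medium = medium,
                              eps = cfg$extraction$eps,
                              bigM = cfg$extraction$big_m)
    say("gap-filling for ", s)
    gf <- gapfillGrowth(ex@model, model, medium = medium,
                        minGrowth = cfg$min_growth)
    kept <- union(reactionIds(ex@model), gf@added)
    filled <- subsetModel(model, kept)
    filled@biomass <- biomassReaction(model)
    writeModel(filled, exFile, "json")
    jsonlite::write_json(list(added = gf@added, growth = gf@growth,
                              objective = ex@objective),
                         gfFile, auto_unbox = TRUE, digits = NA)
    extraction[[s]] <- list(model = filled, kept = kept,
                            objective = ex@objective)
    gapfill[[s]] <- list(added = gf@added, growth = gf@growth)
  }

  ## stage 5: flux response per replicate
  fractions <- seq(cfg$fractions$start, cfg$fractions$stop,
                   length.out = cfg$fractions$steps)
  scans <- list(); growthReactions <- character(0)
  for (s in targetSamples) {
    f <- file.path(outdir, paste0("fluxresponse_", s, ".tsv"))
    m <- applyMedium(extraction[[s]]$model,
                     mediumForModel(medium, extraction[[s]]$model))
    if (resume && file.exists(f)) {
      say("resume: flux response for ", s)
      tb <- utils::read.delim(f, stringsAsFactors = FALSE, comment.char = "#")
      rs <- stats::setNames(tb$r, tb$reaction)
      ga <- names(rs)[!is.na(rs) & rs > cfg$thresholds$r]
      scans[[s]] <- tb
    } else {
      say("flux-response scan for ", s)
      scan <- fluxResponseScan(m, fractions = fractions,
                               mode = cfg$scan_mode)
      writeGrowthAssociation(scan, f)
      ga <- growthAssociatedReactions(scan, rThreshold = cfg$thresholds$r)
      scans[[s]] <- scan
    }
    growthReactions <- union(growthReactions, ga)
  }

  ## stage 6: TF ranking on the union of growth-associated genes
  growthGenes <- genesOfReactions(model,
                                  intersect(growthReactions,
                                            reactionIds(model)))
  tfFile <- file.path(outdir, "tf_ranking.tsv")
  if (resume && file.exists(tfFile)) {
    say("resume: TF ranking")
    tfRanking <- utils::read.delim(tfFile, stringsAsFactors = FALSE)
  } else {
    say("ranking transcription factors")
    tfRanking <- rankTranscriptionFactors(network, growthGenes)
    utils::write.table(tfRanking, tfFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  provenance <- list(
    package = "gemflux",
    version = as.character(utils::packageVersion("gemflux")),
    config = cfg, targetSamples = targetSamples,
    requiredProduction = required)
  jsonlite::write_json(provenance, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(de = de, scores = scores, extraction = extraction,
       gapfill = gapfill, growthAssociation = scans,
       growthReactions = sort(growthReactions),
       growthGenes = growthGenes, tfRanking = tfRanking,
       provenance = provenance)
}
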