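## Model serialisation.
##
## Two formats are supported:
##  * a project JSON dialect, convenient for readable fixtures:
##      {metabolites: [{id, name, compartment}],
##       reactions: [{id, stoich: {met: coef}, lb, ub, gpr, subsystem}],
##       genes: [...], biomass: "..."}
##    Empty GPRs omit the "gpr" key; infinite bounds are written as the
##    strings "inf" / "-inf".
##  * SBML Level 3 Version 1 with the fbc (version 2) package: species,
##    reactions with bound parameters, geneProductAssociation trees and
##    a maximisation objective marking the biomass reaction.  Following
##    the common COBRA convention, species/reaction/gene ids carry
##    M_/R_/G_ prefixes inside the file; the subsystem label travels in
##    a COBRA-style notes element.  Identifiers must be SBML-SId-safe
##    (letters, digits, underscore, not starting with a digit).

SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML <- "http://www.w3.org/1999/xhtml"

#' Read a metabolic model
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"}; by default inferred
#'   from the file extension (\code{.xml}/\code{.sbml} read as SBML).
#' @return a validated \linkS4class{MetabolicModel}.
#' @seealso [writeModel()]
#' @export
readModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") readModelJson(path) else readModelSbml(path)
}

#' Write a metabolic model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"sbml"} (default by extension).
#' @return the path, invisibly.
#' @export
writeModel <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  }
  validObject(model)
  if (format == "json") writeModelJson(model, path) else writeModelSbml(model, path)
  invisible(path)
}

numToJson <- function(x) {
  if (is.infinite(x)) { if (x > 0) "inf" else "-inf" } else x
}
numFromJson <- function(x) {
  if (is.character(x)) { if (x == "inf") Inf else if (x == "-inf") -Inf
                         else as.numeric(x) } else as.numeric(x)
}

writeModelJson <- function(model, path) {
  rids <- colnames(model@S)
  rx <- lapply(rids, function(r) {
    st <- model@S[, r]
    st <- st[st != 0]
    out <- list(id = jsonlite::unbox(r),
                stoich = lapply(as.list(st), jsonlite::unbox),
                lb = jsonlite::unbox(numToJson(model@lb[[r]])),
                ub = jsonlite::unbox(numToJson(model@ub[[r]])))
    if (!isEmptyGpr(model@gpr[[r]]))
      out$gpr <- jsonlite::unbox(model@gpr[[r]]@text)
    if (nzchar(model@subsystem[[r]]))
      out$subsystem <- jsonlite::unbox(model@subsystem[[r]])
    out
  })
  doc <- list(metabolites = model@mets, reactions = rx,
              genes = model@genes, biomass = jsonlite::unbox(model@biomass))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
}

readModelJson <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse error in '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("metabolites", "reactions", "biomass"))
    if (is.null(doc[[f]])) stop("JSON model missing required field '", f, "'")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment)))
  reactions <- list()
  for (r in doc$reactions) {
    if (is.null(r$id)) stop("JSON reaction without an 'id'")
    reactions[[r$id]] <- list(
      stoich = vapply(r$stoich, as.numeric, numeric(1)),
      lb = numFromJson(r$lb), ub = numFromJson(r$ub),
      gpr = r$gpr, subsystem = r$subsystem)
  }
  genes <- if (is.null(doc$genes)) NULL else unlist(doc$genes)
  MetabolicModel(mets, reactions, biomass = doc$biomass, genes = genes)
}

sbmlSafe <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad))
    stop("cannot write SBML: ", what, " id(s) not SId-safe: ",
         paste(utils::head(bad, 3), collapse = ", "))
  ids
}

fmtNum <- function(x) {
  if (is.infinite(x)) { if (x > 0) "INF" else "-INF" }
  else format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

writeModelSbml <- function(model, path) {
  sbmlSafe(model@mets$id, "metabolite")
  sbmlSafe(colnames(model@S), "reaction")
  sbmlSafe(model@genes, "gene")
  sbmlSafe(unique(model@mets$compartment), "compartment")

  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_CORE, "xmlns:fbc" = SBML_FBC,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")

  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in unique(model@mets$compartment))
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")

  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model@mets)))
    xml2::xml_add_child(ls, "species",
                        id = paste0("M_", model@mets$id[i]),
                        name = model@mets$name[i],
                        compartment = model@mets$compartment[i],
                        constant = "false", boundaryCondition = "false",
                        hasOnlySubstanceUnits = "false")

  vals <- sort(unique(c(model@lb, model@ub)))
  pid <- paste0("fb_", seq_along(vals))
  names(pid) <- fmtNum2key(vals)
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_along(vals))
    xml2::xml_add_child(lp, "parameter", id = pid[[i]],
                        value = fmtNum(vals[i]), constant = "true")

  addGpa <- function(parent, e) {
    if (is.character(e)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", e))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", e$op))
      for (a in e$args) addGpa(node, a)
    }
  }

  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in colnames(model@S)) {
    rn <- xml2::xml_add_child(lr, "reaction",
                              id = paste0("R_", r),
                              reversible = tolower(model@lb[[r]] < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = pid[[fmtNum2key(model@lb[[r]])]],
                              "fbc:upperFluxBound" = pid[[fmtNum2key(model@ub[[r]])]])
    if (nzchar(model@subsystem[[r]])) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = XHTML)
      xml2::xml_add_child(body, "p",
                          paste0("SUBSYSTEM: ", model@subsystem[[r]]))
    }
    st <- model@S[, r]
    st <- st[st != 0]
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(st)[st < 0])
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = fmtNum(-st[[m]]),
                            constant = "true")
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(st)[st > 0])
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = fmtNum(st[[m]]),
                            constant = "true")
    }
    if (!isEmptyGpr(model@gpr[[r]])) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      addGpa(gpa, model@gpr[[r]]@expr)
    }
  }

  lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model@biomass),
                      "fbc:coefficient" = "1")

  if (length(model@genes)) {
    lg <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in model@genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", g), "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
}

## bound values keyed by their printed form so -0 and 0 collapse
fmtNum2key <- function(x) vapply(x, fmtNum, character(1))

stripPrefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

readModelSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_CORE, fbc = SBML_FBC)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0) stop("SBML model declares no species")
  mets <- data.frame(
    id = stripPrefix(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  stripPrefix(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"))

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- vapply(xml2::xml_attr(pars, "value"), function(v) {
    if (v == "INF") Inf else if (v == "-INF") -Inf else as.numeric(v)
  }, numeric(1))
  names(pvals) <- xml2::xml_attr(pars, "id")

  parseGpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(stripPrefix(xml2::xml_attr(node, "geneProduct"), "G_"))
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parseGpa)
    if (nm %in% c("and", "or")) list(op = nm, args = args)
    else if (length(args) == 1) args[[1]]
    else stop("unsupported geneProductAssociation node: ", nm)
  }

  rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  for (rn in rxNodes) {
    rid <- stripPrefix(xml2::xml_attr(rn, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- stripPrefix(xml2::xml_attr(sr, "species"), "M_")
      st[m] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- stripPrefix(xml2::xml_attr(sr, "species"), "M_")
      st[m] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !(lbp %in% names(pvals)) ||
        !(ubp %in% names(pvals)))
      stop("reaction '", rid, "' lacks resolvable fbc flux bounds")
    gpaNode <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- NULL
    if (!inherits(gpaNode, "xml_missing")) {
      kids <- xml2::xml_children(gpaNode)
      if (length(kids) == 1) {
        expr <- parseGpa(kids[[1]])
        gpr <- new("GprRule", expr = expr, genes = gprLeaves(expr),
                   text = gprToText(expr))
      }
    }
    subsys <- ""
    p <- xml2::xml_find_first(rn, ".//s:notes//*[starts-with(text(), 'SUBSYSTEM:')]", ns)
    if (inherits(p, "xml_missing"))
      p <- xml2::xml_find_first(rn, ".//s:notes//*[starts-with(., 'SUBSYSTEM:')]", ns)
    if (!inherits(p, "xml_missing"))
      subsys <- trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(p)))
    reactions[[rid]] <- list(stoich = st, lb = unname(pvals[[lbp]]),
                             ub = unname(pvals[[ubp]]), gpr = gpr,
                             subsystem = subsys)
  }

  fo <- xml2::xml_find_first(doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("SBML model lacks an fbc objective (biomass reaction unknown)")
  biomass <- stripPrefix(xml2::xml_attr(fo, "reaction"), "R_")

  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- if (length(gps)) xml2::xml_attr(gps, "label") else NULL

  MetabolicModel(mets, reactions, biomass = biomass, genes = genes)
}
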