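## Omics layer: differential expression under the raw-p + fold-change
## rule, rank-based gene scoring for model extraction, and metabolome
## detection / fold-change classification.

#' Build an expression table
#'
#' Wraps a genes x samples intensity matrix and per-sample group labels
#' into a \code{SummarizedExperiment} (assay \code{"intensity"}, column
#' data field \code{group}).
#'
#' @param intensity numeric matrix, genes in rows (rownames required),
#'   samples in columns (colnames required); linear-scale intensities.
#' @param groups character vector of group labels, one per column.
#' @return a \code{SummarizedExperiment}.
#' @export
ExpressionTable <- function(intensity, groups) {
  stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
            !is.null(colnames(intensity)),
            length(groups) == ncol(intensity))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(intensity)))
}

#' Read an expression table from TSV
#'
#' @param exprPath TSV: first column gene id, remaining columns samples.
#' @param groupsPath two-column TSV mapping \code{sample} to
#'   \code{group} (header required).
#' @return a \code{SummarizedExperiment} (see [ExpressionTable()]).
#' @export
readExpression <- function(exprPath, groupsPath) {
  tb <- utils::read.delim(exprPath, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mat <- as.matrix(tb[, -1, drop = FALSE])
  rownames(mat) <- tb[[1]]
  gr <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(gr)))
    stop("groups file must have columns: sample, group")
  miss <- setdiff(colnames(mat), gr$sample)
  if (length(miss)) stop("samples without group label: ",
                         paste(miss, collapse = ", "))
  ExpressionTable(mat, gr$group[match(colnames(mat), gr$sample)])
}

exprMatrix <- function(se) SummarizedExperiment::assay(se, "intensity")
exprGroups <- function(se) SummarizedExperiment::colData(se)$group

#' Differential expression by Student's t-test plus fold-change gate
#'
#' Per gene: equal-variance two-sample t-test between the two groups and
#' linear-scale fold change \code{mean(groupA) / mean(groupB)}.  A gene
#' is called \code{up} iff p < pThreshold and FC > fcThreshold,
#' \code{down} iff p < pThreshold and FC < 1/fcThreshold, otherwise
#' \code{ns}.  Both gates are strict, so e.g. FC = 1.4 at p = 0.001 is
#' not called.  A Benjamini-Hochberg adjusted p is reported for
#' information only and never gates the call.
#'
#' @param se expression table (see [ExpressionTable()]); intensities
#'   must be positive.
#' @param groupA,groupB group labels (fold change is A over B).
#' @param pThreshold raw p-value threshold (default 0.05).
#' @param fcThreshold fold-change threshold (default 1.5).
#' @return data.frame with columns \code{gene}, \code{fc}, \code{p},
#'   \code{padj}, \code{call}.
#' @export
differentialExpression <- function(se, groupA, groupB,
                                   pThreshold = 0.05, fcThreshold = 1.5) {
  mat <- exprMatrix(se)
  grp <- exprGroups(se)
  for (g in c(groupA, groupB))
    if (sum(grp == g) < 2)
      stop("need at least 2 samples in group '", g, "'")
  if (any(mat[, grp %in% c(groupA, groupB)] <= 0))
    stop("intensities must be positive (linear scale)")
  A <- mat[, grp == groupA, drop = FALSE]
  B <- mat[, grp == groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  se2 <- sp2 * (1 / nA + 1 / nB)
  tt <- (mA - mB) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  ## zero pooled variance: identical groups get p = 1; a noiseless
  ## mean shift is infinitely significant
  degen <- sp2 == 0
  p[degen & mA == mB] <- 1
  p[degen & mA != mB] <- 0
  fc <- mA / mB
  call <- rep("ns", nrow(mat))
  call[p < pThreshold & fc > fcThreshold] <- "up"
  call[p < pThreshold & fc < 1 / fcThreshold] <- "down"
  data.frame(gene = rownames(mat), fc = unname(fc), p = unname(p),
             padj = stats::p.adjust(unname(p), "BH"), call = call,
             row.names = NULL)
}

#' Rank-based gene scores for model extraction
#'
#' Genes are ranked by expression in ascending order: the most highly
#' expressed gene receives rank N (the number of genes), the least
#' expressed rank 1.  The score divides the rank by fraction * N, so
#' with the default fraction 0.3 a gene at the 30th percentile scores
#' exactly 1; genes in the bottom 30% score below 1.  Ties are broken
#' by gene id (lexicographically smaller id gets the smaller rank).
#'
#' @param exprValues named numeric: gene id -> summary expression (mean
#'   over the cell type's replicate samples, or a single sample).
#' @param fraction rank divisor fraction (default 0.3).
#' @return data.frame with columns \code{gene}, \code{rank},
#'   \code{score}, ordered by gene id.
#' @export
rankGeneScores <- function(exprValues, fraction = 0.3) {
  if (length(exprValues) == 0) stop("no genes to score")
  if (is.null(names(exprValues))) stop("exprValues must be named by gene id")
  N <- length(exprValues)
  ord <- order(exprValues, names(exprValues))  # ascending; ties by id
  rank <- integer(N)
  rank[ord] <- seq_len(N)
  out <- data.frame(gene = names(exprValues), rank = rank,
                    score = rank / (fraction * N), row.names = NULL)
  out[order(out$gene), , drop = FALSE]
}

#' Construct a metabolome table
#'
#' @param conc metabolites x replicates numeric matrix; \code{NA} marks
#'   a replicate in which the metabolite was not detected.  Rownames are
#'   metabolite names; column names \code{<type>_<rep>}.
#' @param metClass character per metabolite, \code{"standard"}
#'   (absolute concentrations, pmol per 10^6 cells) or \code{"putative"}
#'   (relative areas).
#' @param cellType cell-type label per column; defaults to the part of
#'   the column name before the last underscore.
#' @return a \linkS4class{MetabolomeTable}.
#' @export
MetabolomeTable <- function(conc, metClass, cellType = NULL) {
  if (is.null(cellType)) cellType <- sub("_[^_]*$", "", colnames(conc))
  if (is.null(names(metClass))) names(metClass) <- rownames(conc)
  new("MetabolomeTable", conc = conc, metClass = metClass,
      cellType = cellType)
}

#' Read a metabolome table from TSV
#'
#' Columns: \code{metabolite}, \code{class}, then replicate columns
#' named \code{<type>_<rep>}.  An empty cell means not detected.
#'
#' @param path file path.
#' @return a \linkS4class{MetabolomeTable}.
#' @export
readMetabolome <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("metabolite", "class") %in% colnames(tb)))
    stop("metabolome file must have columns: metabolite, class, <type>_<rep>...")
  repCols <- setdiff(colnames(tb), c("metabolite", "class"))
  conc <- as.matrix(tb[, repCols, drop = FALSE])
  mode(conc) <- "numeric"
  rownames(conc) <- tb$metabolite
  MetabolomeTable(conc, stats::setNames(tb$class, tb$metabolite))
}

#' Write a metabolome table to TSV
#' @param metab a \linkS4class{MetabolomeTable}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMetabolome <- function(metab, path) {
  df <- data.frame(metabolite = rownames(metab@conc),
                   class = unname(metab@metClass), metab@conc,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Classify metabolite detection across two cell types
#'
#' A metabolite is \code{both} iff detected in every replicate of both
#' cell types; \code{A_only}/\code{B_only} iff detected in every
#' replicate of exactly one type and in no replicate of the other;
#' \code{neither} iff detected in no replicate at all; anything else
#' (partial detection within a type) is \code{irreproducible}.
#'
#' @param metab a \linkS4class{MetabolomeTable}.
#' @param typeA,typeB cell-type labels.
#' @return data.frame with columns \code{metabolite}, \code{category}.
#' @export
classifyDetection <- function(metab, typeA, typeB) {
  for (tp in c(typeA, typeB)) {
    if (sum(metab@cellType == tp) < 2)
      stop("need >= 2 replicates for cell type '", tp, "'")
  }
  detA <- !is.na(metab@conc[, metab@cellType == typeA, drop = FALSE])
  detB <- !is.na(metab@conc[, metab@cellType == typeB, drop = FALSE])
  allA <- rowSums(detA) == ncol(detA); anyA <- rowSums(detA) > 0
  allB <- rowSums(detB) == ncol(detB); anyB <- rowSums(detB) > 0
  category <- rep("irreproducible", nrow(metab@conc))
  category[allA & allB] <- "both"
  category[allA & !anyB] <- "A_only"
  category[allB & !anyA] <- "B_only"
  category[!anyA & !anyB] <- "neither"
  data.frame(metabolite = rownames(metab@conc), category = category,
             row.names = NULL)
}

#' Metabolite fold changes between cell types
#'
#' For metabolites detected in both cell types (category \code{both}),
#' the fold change is the ratio of replicate means, typeA over typeB; a
#' metabolite is flagged when FC > fcThreshold or FC < 1/fcThreshold.
#' Metabolites outside the \code{both} category are excluded with a
#' reason (attribute \code{"excluded"}), never silently dropped and
#' never divided by an undetected mean.
#'
#' @param metab a \linkS4class{MetabolomeTable}.
#' @param typeA,typeB cell-type labels.
#' @param fcThreshold fold-change threshold (default 1.5).
#' @return data.frame with columns \code{metabolite}, \code{fc},
#'   \code{flagged}; excluded metabolites in
#'   \code{attr(, "excluded")}.
#' @export
metaboliteFoldChanges <- function(metab, typeA, typeB, fcThreshold = 1.5) {
  cls <- classifyDetection(metab, typeA, typeB)
  keep <- cls$category == "both"
  A <- metab@conc[keep, metab@cellType == typeA, drop = FALSE]
  B <- metab@conc[keep, metab@cellType == typeB, drop = FALSE]
  fc <- rowMeans(A) / rowMeans(B)
  out <- data.frame(metabolite = cls$metabolite[keep], fc = unname(fc),
                    flagged = unname(fc > fcThreshold | fc < 1 / fcThreshold),
                    row.names = NULL)
  attr(out, "excluded") <- data.frame(
    metabolite = cls$metabolite[!keep],
    reason = sprintf("detection category: %s", cls$category[!keep]),
    row.names = NULL)
  out
}

#' Map detected metabolites to model metabolite ids
#'
#' Metabolites detected in the named cell type (in every replicate; or,
#' with \code{type = NULL}, in every replicate of at least one type) are
#' mapped to model metabolite ids through a synonym table.  Detected
#' metabolites without a synonym entry, and synonyms pointing at ids
#' absent from the model, are reported as unmatched rather than silently
#' dropped.
#'
#' @param metab a \linkS4class{MetabolomeTable}.
#' @param model a \linkS4class{MetabolicModel}.
#' @param synonyms named character: metabolite name -> model metabolite
#'   id (may be empty).
#' @param type cell-type label, or NULL.
#' @return list with \code{matched} (character vector of model
#'   metabolite ids) and \code{unmatched} (character vector of
#'   metabolite names).
#' @export
productionTargets <- function(metab, model, synonyms = character(0),
                              type = NULL) {
  if (nrow(metab@conc) == 0)
    return(list(matched = character(0), unmatched = character(0)))
  if (is.null(type)) {
    detected <- rep(FALSE, nrow(metab@conc))
    for (tp in unique(metab@cellType)) {
      d <- !is.na(metab@conc[, metab@cellType == tp, drop = FALSE])
      detected <- detected | rowSums(d) == ncol(d)
    }
  } else {
    d <- !is.na(metab@conc[, metab@cellType == type, drop = FALSE])
    if (ncol(d) == 0) stop("unknown cell type: ", type)
    detected <- rowSums(d) == ncol(d)
  }
  nm <- rownames(metab@conc)[detected]
  ids <- unname(synonyms[nm])
  ok <- !is.na(ids) & ids %in% metaboliteIds(model)
  list(matched = unique(ids[ok]), unmatched = nm[!ok])
}

#' Read a metabolite synonym table from TSV
#'
#' Two columns with header: \code{metabolite}, \code{model_id}.
#'
#' @param path file path.
#' @return named character vector (metabolite name -> model id).
#' @export
readSynonyms <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "model_id") %in% colnames(tb)))
    stop("synonym file must have columns: metabolite, model_id")
  stats::setNames(tb$model_id, tb$metabolite)
}
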