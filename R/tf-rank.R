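## Transcription-factor prioritisation: load a TF -> target edge table
## (RegNetwork-style) and rank TFs by how many growth-associated
## metabolic genes they target.

#' Construct a regulatory network
#'
#' @param edges data.frame with columns \code{TF}, \code{target},
#'   \code{confidence}, \code{evidence}; duplicate (TF, target) pairs
#'   are collapsed.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
RegulatoryNetwork <- function(edges) {
  need <- c("TF", "target", "confidence", "evidence")
  miss <- setdiff(need, colnames(edges))
  if (length(miss))
    stop("edge table missing required column(s): ",
         paste(miss, collapse = ", "))
  edges <- edges[!duplicated(edges[, c("TF", "target")]), need, drop = FALSE]
  rownames(edges) <- NULL
  targets <- split(edges$target, edges$TF)
  new("RegulatoryNetwork", edges = edges, targets = targets)
}

#' @export
setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", nrow(object@edges), "edges,",
      length(object@targets), "TFs\n")
})

#' Load a regulatory network from TSV
#'
#' Tab-separated file with header columns \code{TF}, \code{target},
#' \code{confidence}, \code{evidence}.  Rows whose confidence label is
#' not in \code{confidenceFilter} are dropped (e.g. keep only
#' high-confidence, experimentally supported interactions); duplicate
#' edges collapse to one.
#'
#' @param path file path.
#' @param confidenceFilter character vector of confidence labels to
#'   keep, or NULL to keep everything.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
loadRegulatoryNetwork <- function(path, confidenceFilter = NULL) {
  tb <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read network file '",
                                          path, "': ", conditionMessage(e)))
  need <- c("TF", "target", "confidence", "evidence")
  miss <- setdiff(need, colnames(tb))
  if (length(miss))
    stop("network file missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!nzchar(tb$TF) | !nzchar(tb$target) | is.na(tb$TF) |
                 is.na(tb$target))
  if (length(bad))
    stop("malformed network row (empty TF or target) at line ",
         bad[1] + 1L)
  if (!is.null(confidenceFilter))
    tb <- tb[tb$confidence %in% confidenceFilter, , drop = FALSE]
  RegulatoryNetwork(tb)
}

#' Rank transcription factors by growth-associated target coverage
#'
#' For each TF the count is the number of distinct growth-associated
#' genes among its targets.  TFs with no overlap are excluded; ties are
#' ordered lexicographically by TF id.  The growth-associated gene set
#' is typically obtained with [genesOfReactions()] on the output of
#' [growthAssociatedReactions()].
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param growthGenes character vector of growth-associated gene ids.
#' @return data.frame with columns \code{rank}, \code{TF}, \code{count},
#'   \code{overlap} (comma-joined gene ids), ordered by decreasing
#'   count.
#' @export
rankTranscriptionFactors <- function(network, growthGenes) {
  growthGenes <- unique(growthGenes)
  if (length(growthGenes) == 0)
    return(data.frame(rank = integer(0), TF = character(0),
                      count = integer(0), overlap = character(0)))
  ov <- lapply(network@targets, function(tg) sort(intersect(tg, growthGenes)))
  counts <- vapply(ov, length, integer(1))
  keep <- counts > 0
  ov <- ov[keep]; counts <- counts[keep]
  ord <- order(-counts, names(counts))
  data.frame(rank = seq_along(ord), TF = names(counts)[ord],
             count = unname(counts[ord]),
             overlap = vapply(ov[ord], paste, character(1), collapse = ","),
             row.names = NULL)
}

#' Write a TF ranking to TSV
#' @param ranking data.frame from [rankTranscriptionFactors()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTfRanking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
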