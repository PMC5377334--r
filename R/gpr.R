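#' Parse a gene-protein-reaction rule
#'
#' Parses boolean rule text over gene identifiers with \code{and} /
#' \code{or} connectives (case-insensitive) and parentheses.  The usual
#' biochemical reading applies: AND joins subunits of a complex, OR
#' joins isoenzymes.  An empty or whitespace-only string yields the
#' distinguished empty rule (reaction without gene association).
#'
#' @param text rule text, e.g. \code{"(G1 and G2) or G3"}.
#' @return a \linkS4class{GprRule}.
#' @examples
#' r <- parseGpr("(G1 and G2) or G3")
#' evalGpr(r, "G3")
#' @export
parseGpr <- function(text) {
  if (length(text) != 1 || is.na(text)) stop("rule text must be a single string")
  if (!nzchar(trimws(text))) return(emptyGpr())

  ## tokenize, keeping character offsets for error messages
  toks <- list()
  i <- 1L; nch <- nchar(text)
  while (i <= nch) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= nch && !grepl("^[\\s()]$", substr(text, j, j), perl = TRUE))
        j <- j + 1L
      word <- substr(text, i, j - 1L)
      type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
      toks[[length(toks) + 1L]] <- list(type = type, value = word, pos = i)
      i <- j
    }
  }

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg, at) {
    stop(sprintf("GPR parse error at position %d: %s", at, msg), call. = FALSE)
  }

  parsePrimary <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of rule", nch + 1L)
    if (t$type == "(") {
      open <- advance()
      e <- parseOr()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")")
        fail("unbalanced parentheses (missing ')')", open$pos)
      advance()
      return(e)
    }
    if (t$type == "gene") { advance(); return(t$value) }
    fail(sprintf("dangling operator '%s'", t$value), t$pos)
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (!is.null(t <- peek()) && t$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parsePrimary()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.null(t <- peek()) && t$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parseAnd()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }

  e <- parseOr()
  t <- peek()
  if (!is.null(t))
    fail(if (t$type == ")") "unbalanced parentheses (stray ')')"
         else sprintf("unexpected token '%s'", t$value %||% t$type), t$pos)
  new("GprRule", expr = e, genes = gprLeaves(e), text = gprToText(e))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gprLeaves <- function(e) {
  if (is.null(e)) character(0)
  else if (is.character(e)) e
  else unique(unlist(lapply(e$args, gprLeaves)))
}

gprToText <- function(e) {
  if (is.null(e)) return("")
  if (is.character(e)) return(e)
  parts <- vapply(e$args, function(a) {
    s <- gprToText(a)
    if (is.list(a) && a$op != e$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", e$op, " "))
}

#' The empty GPR rule
#'
#' @return a \linkS4class{GprRule} with no gene association.
#' @export
emptyGpr <- function() new("GprRule", expr = NULL, genes = character(0), text = "")

#' Test whether a GPR rule is empty
#' @param rule a \linkS4class{GprRule}.
#' @return logical scalar.
#' @export
isEmptyGpr <- function(rule) is.null(rule@expr)

#' Evaluate a GPR rule against a set of present genes
#'
#' Standard boolean semantics: a gene leaf is TRUE iff the gene is in
#' \code{present}; AND/OR combine as usual.  The empty rule evaluates
#' TRUE (gene-independent reaction).
#'
#' @param rule a \linkS4class{GprRule}.
#' @param present character vector of present (expressed/active) genes.
#' @return logical scalar: is the reaction active?
#' @export
evalGpr <- function(rule, present) {
  rec <- function(e) {
    if (is.null(e)) return(TRUE)
    if (is.character(e)) return(e %in% present)
    vals <- vapply(e$args, rec, logical(1))
    if (e$op == "and") all(vals) else any(vals)
  }
  rec(rule@expr)
}

#' Aggregate per-gene scores through a GPR rule
#'
#' Isoenzymes (OR) take the best available gene score (max); complex
#' subunits (AND) are limited by the weakest one (min).  Genes missing
#' from \code{scores} contribute \code{missing}.
#'
#' @param rule a \linkS4class{GprRule}.
#' @param scores named numeric, gene id -> score.
#' @param missing value substituted for genes without a score.
#' @return numeric scalar, or \code{NA} for the empty rule.
#' @export
aggregateGpr <- function(rule, scores, missing = 1) {
  rec <- function(e) {
    if (is.character(e)) {
      if (e %in% names(scores)) unname(scores[[e]]) else missing
    } else {
      vals <- vapply(e$args, rec, numeric(1))
      if (e$op == "and") min(vals) else max(vals)
    }
  }
  if (isEmptyGpr(rule)) return(NA_real_)
  rec(rule@expr)
}

#' @describeIn parseGpr display method
#' @param object a \linkS4class{GprRule}.
#' @export
setMethod("show", "GprRule", function(object) {
  if (isEmptyGpr(object)) cat("GprRule: <no gene association>\n")
  else cat("GprRule:", object@text, "\n")
})
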