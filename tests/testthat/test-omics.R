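# Differential expression, rank scoring, metabolome classification.

makeExpr <- function(values) {
  # values: list(gene = c(a1, a2, b1, b2))
  mat <- do.call(rbind, values)
  colnames(mat) <- c("A_1", "A_2", "B_1", "B_2")
  ExpressionTable(mat, c("A", "A", "B", "B"))
}

test_that("DE applies the raw-p and fold-change gates strictly", {
  se <- makeExpr(list(
    up = c(200, 202, 100, 101),       # planted 2-fold, near-zero noise
    flat = c(100, 100, 100, 100),     # identical groups
    small = c(140.0, 140.0001, 100, 100.0001))) # tiny p, FC 1.4
  de <- differentialExpression(se, "A", "B")
  expect_identical(de$call[de$gene == "up"], "up")
  expect_gt(de$fc[de$gene == "up"], 1.9)
  expect_identical(de$call[de$gene == "flat"], "ns")
  expect_equal(de$p[de$gene == "flat"], 1)
  # fold-change gate fails even at tiny p
  expect_lt(de$p[de$gene == "small"], 0.001)
  expect_identical(de$call[de$gene == "small"], "ns")
})

test_that("DE p-values match the reference t computation to 1e-10", {
  set.seed(42)
  mat <- matrix(rlnorm(200, log(100), 0.3), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50),
                                c("A_1", "A_2", "B_1", "B_2")))
  se <- ExpressionTable(mat, c("A", "A", "B", "B"))
  de <- differentialExpression(se, "A", "B")
  ref <- apply(mat, 1, function(x)
    stats::t.test(x[1:2], x[3:4], var.equal = TRUE)$p.value)
  expect_equal(de$p, unname(ref), tolerance = 1e-10)
  refFc <- rowMeans(mat[, 1:2]) / rowMeans(mat[, 3:4])
  expect_equal(de$fc, unname(refFc), tolerance = 1e-12)
})

test_that("DE rejects invalid input", {
  se <- makeExpr(list(g = c(100, -1, 100, 100)))
  expect_error(differentialExpression(se, "A", "B"), "positive")
  one <- ExpressionTable(matrix(c(1, 2), 1, 2,
                                dimnames = list("g", c("s1", "s2"))),
                         c("A", "B"))
  expect_error(differentialExpression(one, "A", "B"), "at least 2 samples")
})

test_that("rank scores follow score = rank / (fraction * N) exactly", {
  vals <- setNames(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                   paste0("g", sprintf("%02d", 1:10)))
  sc <- rankGeneScores(vals, fraction = 0.3)
  expect_identical(sort(sc$rank), 1:10)
  # most expressed gene: rank N, score N/(0.3 N)
  expect_equal(sc$score[sc$gene == "g10"], 10 / 3, tolerance = 1e-15)
  # the 30th-percentile gene scores exactly 1
  expect_identical(sc$score[sc$rank == 3], 1)
  expect_equal(sc$score[sc$rank == 1], 1 / 3, tolerance = 1e-15)
  expect_identical(sc$score, sc$rank / (0.3 * 10))
})

test_that("rank ties break lexicographically and scores are scale-invariant", {
  vals <- c(b = 5, a = 5, c = 1)
  sc <- rankGeneScores(vals)
  expect_identical(sc$rank[sc$gene == "a"], 2L)
  expect_identical(sc$rank[sc$gene == "b"], 3L)
  expect_identical(sc$rank[sc$gene == "c"], 1L)
  set.seed(1)
  vals2 <- setNames(rlnorm(30), paste0("g", 1:30))
  sc1 <- rankGeneScores(vals2)
  sc2 <- rankGeneScores(vals2 * 17.3)
  expect_identical(sc1, sc2)
  expect_error(rankGeneScores(numeric(0)), "no genes")
})

makeMetab <- function(rows) {
  conc <- do.call(rbind, rows)
  colnames(conc) <- c("A_1", "A_2", "B_1", "B_2")
  MetabolomeTable(conc, setNames(rep("standard", length(rows)), names(rows)))
}

test_that("detection categories follow the replicate rules and partition", {
  mt <- makeMetab(list(
    both = c(10, 12, 9, 11),
    aonly = c(10, 12, NA, NA),
    bonly = c(NA, NA, 9, 11),
    none = c(NA, NA, NA, NA),
    irre = c(10, NA, NA, NA),
    irre2 = c(10, 12, 9, NA)))
  cls <- classifyDetection(mt, "A", "B")
  got <- setNames(cls$category, cls$metabolite)
  expect_identical(unname(got[c("both", "aonly", "bonly", "none",
                                "irre", "irre2")]),
                   c("both", "A_only", "B_only", "neither",
                     "irreproducible", "irreproducible"))
  # partition: every metabolite appears in exactly one category
  expect_identical(sort(cls$metabolite), sort(rownames(mt@conc)))
  expect_false(any(duplicated(cls$metabolite)))
  expect_error(classifyDetection(mt, "A", "NOPE"), "NOPE")
})

test_that("fold changes are computed only for 'both' metabolites", {
  mt <- makeMetab(list(
    hi = c(30, 32, 10, 10),
    flat = c(10, 10, 10, 10),
    aonly = c(10, 12, NA, NA)))
  fc <- metaboliteFoldChanges(mt, "A", "B")
  expect_equal(fc$fc[fc$metabolite == "hi"], 3.1, tolerance = 1e-12)
  expect_true(fc$flagged[fc$metabolite == "hi"])
  expect_equal(fc$fc[fc$metabolite == "flat"], 1)
  expect_false(fc$flagged[fc$metabolite == "flat"])
  # exclusive detection is routed out with a reason, no division by zero
  expect_false("aonly" %in% fc$metabolite)
  excl <- attr(fc, "excluded")
  expect_identical(excl$metabolite, "aonly")
  expect_match(excl$reason, "A_only")
  # symmetric flagging below 1/threshold
  mt2 <- makeMetab(list(lo = c(10, 10, 30, 32)))
  expect_true(metaboliteFoldChanges(mt2, "A", "B")$flagged)
})

test_that("production targets map through synonyms and report unmatched", {
  m <- chainModel()
  mt <- makeMetab(list(lactate = c(5, 6, 4, 5), mystery = c(1, 2, 1, 2)))
  res <- productionTargets(mt, m, c(lactate = "B"))
  expect_identical(res$matched, "B")
  expect_identical(res$unmatched, "mystery")
  empty <- MetabolomeTable(
    matrix(numeric(0), 0, 4,
           dimnames = list(NULL, c("A_1", "A_2", "B_1", "B_2"))),
    setNames(character(0), character(0)))
  res0 <- productionTargets(empty, m, c(lactate = "B"))
  expect_identical(res0$matched, character(0))
  expect_identical(res0$unmatched, character(0))
  # per-type detection: metabolite absent from one type is not a target there
  mt2 <- makeMetab(list(aonly = c(5, 6, NA, NA)))
  expect_identical(productionTargets(mt2, m, c(aonly = "B"), type = "B")$matched,
                   character(0))
  expect_identical(productionTargets(mt2, m, c(aonly = "B"), type = "A")$matched,
                   "B")
})

test_that("expression and metabolome TSV readers round trip", {
  spec <- syntheticSpec(seed = 5)
  bundle <- generateBundle(spec)
  dir <- withr::local_tempdir()
  writeBundle(bundle, dir)
  se <- readExpression(file.path(dir, "expression.tsv"),
                       file.path(dir, "groups.tsv"))
  expect_equal(SummarizedExperiment::assay(se),
               SummarizedExperiment::assay(bundle$expression),
               tolerance = 1e-12)
  mt <- readMetabolome(file.path(dir, "metabolome.tsv"))
  expect_equal(mt@conc, bundle$metabolome@conc, tolerance = 1e-12)
  expect_identical(mt@metClass, bundle$metabolome@metClass)
  syn <- readSynonyms(file.path(dir, "synonyms.tsv"))
  expect_identical(syn, bundle$synonyms)
})
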