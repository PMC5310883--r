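# Enrichment scores, fold statistics, proportions and trend flags.

twoTermTable <- function(es) EnrichmentTable(es)

test_that("abundance-mode scores are sums of log2(e + 1) over annotated genes", {
  ann <- annSet(list(g1 = "GO:0000010", g2 = "GO:0000010",
                     g3 = "GO:0000011"))
  e <- exprMat(matrix(c(3, 1, 9,
                        0, 0, 0), nrow = 3,
                      dimnames = list(c("g1", "g2", "g3"),
                                      c("S1", "S2"))))
  es <- esMatrix(enrichmentScores(e, ann))
  expect_equal(es["GO:0000010", "S1"], log2(4) + log2(2))  # 3.0
  expect_equal(es["GO:0000011", "S1"], log2(10))
  # e = 0 contributes log2(1) = 0: an all-zero sample scores 0 everywhere
  expect_equal(unname(es[, "S2"]), c(0, 0))
})

test_that("log-fold-change mode weights by log2(2^e + 1), indicator applied", {
  ann <- annSet(list(g1 = "GO:0000010", g2 = "GO:0000011"))
  e <- exprMat(matrix(c(0, 2, 1, -1), nrow = 2,
                      dimnames = list(c("g1", "g2"), c("S1", "S2"))),
               mode = "log_fold_change")
  es <- esMatrix(enrichmentScores(e, ann))
  # a zero-change gene still adds one unit
  expect_equal(es["GO:0000010", "S1"], 1.0)
  # the indicator keeps the two terms' scores distinct
  expect_equal(es["GO:0000011", "S1"], log2(2^2 + 1))
  expect_false(es["GO:0000010", "S2"] == es["GO:0000011", "S2"])
})

test_that("both weighting modes are monotone increasing in expression", {
  ann <- annSet(list(g1 = "GO:0000010"))
  for (mode in c("abundance", "log_fold_change")) {
    vals <- if (mode == "abundance") c(0, 1, 5, 50) else c(-3, 0, 1, 4)
    e <- exprMat(matrix(vals, nrow = 1,
                        dimnames = list("g1", paste0("S", 1:4))),
                 mode = mode)
    es <- esMatrix(enrichmentScores(e, ann))
    expect_true(all(diff(es[1, ]) > 0))
  }
})

test_that("genes absent from annotations or expression contribute nothing", {
  ann <- annSet(list(g1 = "GO:0000010", ghost = "GO:0000010"))
  e <- exprMat(matrix(c(3, 5, 3, 5), nrow = 2,
                      dimnames = list(c("g1", "gX"), c("S1", "S2"))))
  es <- esMatrix(enrichmentScores(e, ann))
  expect_equal(es["GO:0000010", "S1"], log2(4))  # only g1 counts
  expect_error(enrichmentScores(e, annSet(list())),
               class = "ewgo_domain_error")
})

test_that("stepwise folds are consecutive ES ratios; zero scores exclude", {
  tab <- stepwiseFold(twoTermTable(matrix(
    c(2, 4, 8,
      5, 5, 5,
      0, 4, 4), nrow = 3, byrow = TRUE,
    dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))))
  fs <- foldSteps(tab)
  expect_equal(unname(fs["a", ]), c(2, 2))
  expect_equal(unname(fs["b", ]), c(1, 1))
  expect_true(all(is.na(fs["c", ])))
  expect_equal(unname(isIncluded(tab)), c(TRUE, TRUE, FALSE))
  expect_error(stepwiseFold(twoTermTable(matrix(1, 1, 1,
    dimnames = list("a", "S1")))), class = "ewgo_domain_error")
})

test_that("average fold is the geometric mean and telescopes", {
  tab <- averageFold(twoTermTable(matrix(
    c(2, 4, 8,
      8, 1, 8), nrow = 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("S1", "S2", "S3")))))
  expect_equal(unname(avgFoldLinear(tab)["a"]), 2)
  expect_equal(unname(avgFoldLog(tab)["a"]), 1)
  # telescoping: only first and last samples matter for the average
  expect_equal(unname(avgFoldLinear(tab)["b"]), 1)
  expect_equal(unname(avgFoldLog(tab)["b"]), 0)
})

test_that("average fold matches a brute-force geometric-mean oracle", {
  set.seed(11)
  for (rep in 1:20) {
    K <- sample(3:6, 1)
    es <- matrix(runif(4 * K, 0.1, 50), nrow = 4,
                 dimnames = list(paste0("t", 1:4), paste0("S", 1:K)))
    tab <- averageFold(twoTermTable(es))
    for (t in rownames(es)) {
      ratios <- es[t, -1] / es[t, -K]
      oracle <- prod(ratios)^(1 / (K - 1))
      expect_equal(unname(avgFoldLinear(tab)[t]), oracle,
                   tolerance = 1e-12)
      expect_equal(2^unname(avgFoldLog(tab)[t]), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("proportions normalize each sample to 1 over the chosen subset", {
  es <- matrix(c(3, 1, 6, 2), nrow = 2,
               dimnames = list(c("t1", "t2"), c("S1", "S2")))
  tab <- enrichmentProportions(twoTermTable(es))
  expect_equal(unname(epMatrix(tab)[, "S1"]), c(0.75, 0.25))
  expect_equal(unname(colSums(epMatrix(tab))), c(1, 1))

  # single-term subset -> proportion 1 everywhere
  tab1 <- enrichmentProportions(twoTermTable(es), "t1")
  expect_equal(unname(epMatrix(tab1)["t1", ]), c(1, 1))

  set.seed(5)
  for (rep in 1:10) {
    es <- matrix(runif(12, 0.01, 9), nrow = 4,
                 dimnames = list(paste0("t", 1:4), paste0("S", 1:3)))
    ep <- epMatrix(enrichmentProportions(twoTermTable(es)))
    expect_equal(unname(colSums(ep)), rep(1, 3), tolerance = 1e-12)
  }
  zero <- matrix(c(0, 1, 0, 1), nrow = 2,
                 dimnames = list(c("t1", "t2"), c("S1", "S2")))
  zero[, 1] <- 0
  expect_error(enrichmentProportions(twoTermTable(zero)),
               class = "ewgo_domain_error")
})

test_that("monotone flags use non-strict inequalities", {
  tab <- monotonePatterns(twoTermTable(matrix(
    c(1, 2, 2, 5,
      3, 3, 3, 3,
      1, 5, 2, 2,
      9, 7, 7, 1), nrow = 4, byrow = TRUE,
    dimnames = list(paste0("t", 1:4), paste0("S", 1:4)))))
  rd <- SummarizedExperiment::rowData(tab)
  expect_equal(unname(rd$monotoneUp), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(rd$monotoneDown), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("with propagated annotations, parent scores dominate child scores", {
  for (seed in 1:5) {
    sim <- simulateScenario(randomScenario(seed))
    ann <- propagateAnnotations(sim$annotations, sim$graph)
    es <- esMatrix(enrichmentScores(sim$expr, ann))
    e <- goEdges(sim$graph)
    for (i in seq_len(nrow(e))) {
      if (all(c(e$child[i], e$parent[i]) %in% rownames(es)))
        expect_true(all(es[e$parent[i], ] >= es[e$child[i], ] - 1e-12))
    }
  }
})

test_that("sample order matters stepwise but telescopes in the average", {
  set.seed(21)
  es <- matrix(runif(5 * 4, 0.5, 20), nrow = 5,
               dimnames = list(paste0("t", 1:5), paste0("S", 1:4)))
  base <- averageFold(twoTermTable(es))
  # permuting interior samples: stepwise folds change, the average does not
  perm <- averageFold(twoTermTable(es[, c(1, 3, 2, 4)]))
  expect_false(isTRUE(all.equal(unname(foldSteps(base)),
                                unname(foldSteps(perm)))))
  expect_equal(avgFoldLinear(perm), avgFoldLinear(base), tolerance = 1e-12)
  # swapping first and last (or full reversal) negates the log average
  rev1 <- averageFold(twoTermTable(es[, c(4, 2, 3, 1)]))
  expect_equal(avgFoldLog(rev1), -avgFoldLog(base), tolerance = 1e-12)
  rev2 <- averageFold(twoTermTable(es[, 4:1]))
  expect_equal(avgFoldLog(rev2), -avgFoldLog(base), tolerance = 1e-12)
})

test_that("a 2^c scaling of (e+1) in one sample shifts ES by c per gene", {
  ann <- annSet(list(g1 = "GO:0000010", g2 = "GO:0000010"))
  v <- matrix(c(3, 7, 3, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("S1", "S2")))
  c0 <- 1.5
  v[, 2] <- (v[, 1] + 1) * 2^c0 - 1
  es <- esMatrix(enrichmentScores(exprMat(v), ann))
  expect_equal(es["GO:0000010", "S2"] - es["GO:0000010", "S1"], 2 * c0,
               tolerance = 1e-12)
})

test_that("negative abundance and duplicate genes are validation errors", {
  expect_error(ExpressionMatrix(matrix(c(-1, 2), 1, 2,
    dimnames = list("g1", c("S1", "S2")))),
    "g1.*S1", class = "ewgo_validation_error")
  m <- matrix(1, 2, 2, dimnames = list(c("g1", "g1"), c("S1", "S2")))
  expect_error(ExpressionMatrix(m), class = "ewgo_validation_error")
})
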