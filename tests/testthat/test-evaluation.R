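mkGold <- function(genes, edges) {
  GoldStandard(if (length(edges)) do.call(rbind, edges) else NULL, genes)
}

test_that("perfect and uninformative rankings hit the anchor values", {
  genes <- c("A", "B", "C")
  gold <- mkGold(genes, list(c("A", "B"), c("B", "C")))
  # give the two true edges the largest |score|
  scoreFor <- function(r, t) if (paste(r, t) %in% c("A B", "B C")) 5 else 0.1
  pairs <- expand.grid(target = genes, regulator = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  sc <- mapply(scoreFor, pairs$regulator, pairs$target)
  tab <- edgeTable(data.frame(regulator = pairs$regulator,
                              target = pairs$target, score = sc))
  res <- evaluateRanking(tab, gold)
  expect_equal(auroc(res), 1)
  expect_equal(aupr(res), 1)

  flat <- edgeTable(data.frame(regulator = pairs$regulator,
                               target = pairs$target, score = 1))
  expect_equal(auroc(evaluateRanking(flat, gold)), 0.5)
})

test_that("the four-candidate toy gives AUROC 0.75 and AUPR 5/6", {
  m <- rankingMetrics(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(m$auroc, 0.75)
  expect_equal(m$aupr, (1 / 1 + 2 / 3) / 2)
  # cross-check against the pairwise concordance oracle
  expect_equal(m$auroc, concordanceAUROC(c(4, 3, 2, 1),
                                         c(TRUE, FALSE, TRUE, FALSE)))
  # all-tied scores fall back to one half
  expect_equal(rankingMetrics(rep(1, 6), rep(c(TRUE, FALSE), 3))$auroc, 0.5)
})

test_that("AUROC equals the pairwise concordance oracle", {
  set.seed(3)
  genes <- paste0("G", 1:10)
  for (rep in 1:20) {
    nT <- sample(1:40, 1)
    pairs <- expand.grid(target = genes, regulator = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    truthIdx <- sample(nrow(pairs), nT)
    gold <- mkGold(genes, lapply(truthIdx, function(i)
      c(pairs$regulator[i], pairs$target[i])))
    # mix of continuous and heavily tied scores
    sc <- if (rep %% 2) rnorm(90) else sample(c(-2, -1, 0, 1, 2), 90, TRUE)
    tab <- edgeTable(data.frame(regulator = pairs$regulator,
                                target = pairs$target, score = sc))
    res <- evaluateRanking(tab, gold)
    key <- paste(pairs$regulator, pairs$target)
    truth <- key %in% paste(pairs$regulator[truthIdx], pairs$target[truthIdx])
    expect_equal(auroc(res), concordanceAUROC(abs(sc), truth))
  }
})

test_that("reversing a tie-free ranking flips AUROC around one half", {
  set.seed(4)
  genes <- paste0("G", 1:6)
  pairs <- expand.grid(target = genes, regulator = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  gold <- mkGold(genes, lapply(sample(nrow(pairs), 7), function(i)
    c(pairs$regulator[i], pairs$target[i])))
  # strictly positive, distinct scores so |score| reversal is exact
  sc <- sort(runif(30, 0.1, 1)) * sample(c(1), 30, TRUE)
  tab <- edgeTable(data.frame(regulator = pairs$regulator,
                              target = pairs$target, score = sc))
  rev <- edgeTable(data.frame(regulator = pairs$regulator,
                              target = pairs$target, score = 1 / sc))
  a1 <- auroc(evaluateRanking(tab, gold))
  a2 <- auroc(evaluateRanking(rev, gold))
  expect_equal(a1 + a2, 1)
})

test_that("random rankings average an AUROC of one half", {
  set.seed(5)
  genes <- paste0("G", 1:8)
  pairs <- expand.grid(target = genes, regulator = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  gold <- mkGold(genes, lapply(sample(nrow(pairs), 10), function(i)
    c(pairs$regulator[i], pairs$target[i])))
  aurocs <- vapply(1:200, function(i) {
    tab <- edgeTable(data.frame(regulator = pairs$regulator,
                                target = pairs$target, score = rnorm(56)))
    auroc(evaluateRanking(tab, gold))
  }, 1)
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})

test_that("degenerate inputs are rejected", {
  genes <- c("A", "B", "C")
  pairs <- expand.grid(target = genes, regulator = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  tab <- edgeTable(data.frame(regulator = pairs$regulator,
                              target = pairs$target, score = rnorm(6)))
  expect_error(evaluateRanking(tab, mkGold(genes, list())), "no true edges")
  short <- edgeTable(edgeEntries(tab)[-1L, ])
  expect_error(evaluateRanking(short, mkGold(genes, list(c("A", "B")))),
               "missing candidate")
})

test_that("file-level evaluation matches the in-memory path exactly", {
  sim <- dream4Fixture(seed = 3)
  genes <- geneNames(sim$data)
  set.seed(6)
  tab <- fullRanking(genes, rnorm(90))
  rf <- withr::local_tempfile(); gf <- withr::local_tempfile()
  writeEdgeRanking(tab, rf)
  e <- trueEdges(sim$gold)
  writeLines(paste(e[, 1L], e[, 2L], "1", sep = "\t"), gf)
  fileRes <- evaluateFiles(rf, gf, genes)
  # in-memory result on the file-precision scores
  memRes <- evaluateRanking(readEdgeRanking(rf), sim$gold)
  expect_equal(auroc(fileRes), auroc(memRes), tolerance = 1e-12)
  expect_equal(aupr(fileRes), aupr(memRes), tolerance = 1e-12)
  expect_error(evaluateFiles(rf, gf, genes[-1L]), "unknown gene|missing")
})
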