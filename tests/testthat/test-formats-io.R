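test_that("a single-block file parses into one series", {
  f <- withr::local_tempfile()
  writeLines(c("Time\tG1\tG2", "0\t1.5\t-2", "10\t2.5\t0.25", "20\t3\t1e-2"), f)
  ts <- readTimeSeries(f)
  expect_equal(nSeries(ts), 1L)
  expect_equal(geneNames(ts), c("G1", "G2"))
  expect_equal(nTimePoints(ts), 3L)
  # values are transposed to genes x times
  expect_equal(seriesValues(ts, 1L),
               matrix(c(1.5, 2.5, 3, -2, 0.25, 0.01), 2, 3, byrow = TRUE,
                      dimnames = list(c("G1", "G2"), NULL)))
  expect_equal(ts@series[[1L]]@timePoints, c(0, 10, 20))
})

test_that("blank-line-separated blocks become separate series", {
  f <- withr::local_tempfile()
  block <- function(n, off) c("Time\tG1\tG2\tG3",
                              paste(seq_len(n) - 1, off + seq_len(n),
                                    2 * seq_len(n), 3, sep = "\t"))
  writeLines(c(block(20, 0), "", block(20, 100)), f)
  ts <- readTimeSeries(f)
  expect_equal(nSeries(ts), 2L)
  expect_equal(nTimePoints(ts), c(20L, 20L))
  # second block may omit the repeated header
  f2 <- withr::local_tempfile()
  writeLines(c("Time\tG1\tG2\tG3", "0\t1\t2\t3", "1\t4\t5\t6", "",
               "0\t7\t8\t9", "1\t1\t1\t1"), f2)
  expect_equal(nSeries(readTimeSeries(f2)), 2L)
})

test_that("malformed time-series files fail with located errors", {
  f <- withr::local_tempfile()
  writeLines(c("Time\tG1\tG2", "0\t1\t2", "1\t3"), f)
  expect_error(readTimeSeries(f), "line 3")
  writeLines(c("Time\tG1\tG2", "0\t1\tfoo"), f)
  expect_error(readTimeSeries(f), "non-numeric.*foo")
  writeLines(c("Time\tG1\tG2", "0\t1\t2", "1\t2\t3", "",
               "Time\tG2\tG1", "0\t1\t2", "1\t2\t3"), f)
  expect_error(readTimeSeries(f), "same genes in the same order")
  expect_error(readTimeSeries(file.path(tempdir(), "absent.tsv")),
               "not found")
})

test_that("multiple files act like multiple blocks", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c("Time\tG1\tG2", "0\t1\t2", "1\t3\t4"), f1)
  writeLines(c("Time\tG1\tG2", "0\t5\t6", "1\t7\t8"), f2)
  ts <- readTimeSeries(c(f1, f2))
  expect_equal(nSeries(ts), 2L)
  expect_equal(seriesValues(ts, 2L)[, 1L], c(G1 = 5, G2 = 6))
})

test_that("gold standards read edges, negatives, and reject bad input", {
  f <- withr::local_tempfile()
  writeLines(c("G1\tG2\t1", "G2\tG3\t0"), f)
  gs <- readGoldStandard(f, c("G1", "G2", "G3"))
  expect_equal(trueEdges(gs), matrix(c("G1", "G2"), 1,
               dimnames = list(NULL, c("regulator", "target"))))
  expect_equal(length(geneUniverse(gs)), 3L)

  writeLines(character(), f)
  gs0 <- readGoldStandard(f, paste0("G", 1:10))
  expect_equal(nrow(trueEdges(gs0)), 0L)

  writeLines("G1\tG1\t1", f)
  expect_error(readGoldStandard(f, c("G1", "G2")), "self-edge")
  writeLines("G1\tG9\t1", f)
  expect_error(readGoldStandard(f, c("G1", "G2")), "G9")
  writeLines(c("G1\tG2\t1", "G1\tG2\t0"), f)
  expect_error(readGoldStandard(f, c("G1", "G2")), "contradictory")
})

test_that("edge rankings write in |score| order and round-trip exactly", {
  t2 <- edgeTable(data.frame(regulator = c("G1", "G2"),
                             target = c("G2", "G1"),
                             score = c(3, -5)))
  f <- withr::local_tempfile()
  writeEdgeRanking(t2, f)
  lines <- readLines(f)
  expect_match(lines[1L], "^G2\tG1\t-5")

  empty <- new("EdgeScoreTable",
               entries = data.frame(regulator = character(),
                                    target = character(), score = numeric()),
               bestK = 1L, clusterScores = matrix(numeric(), 0, 0))
  expect_error(writeEdgeRanking(empty, f), "empty")

  set.seed(7)
  genes <- paste0("G", 1:10)
  big <- fullRanking(genes, rnorm(90))
  writeEdgeRanking(big, f)
  back <- readEdgeRanking(f)
  expect_identical(edgeEntries(back)$regulator, edgeEntries(big)$regulator)
  expect_identical(edgeEntries(back)$target, edgeEntries(big)$target)
})

test_that("time-series writer output re-reads to full printed precision", {
  sim <- dream4Fixture(seed = 11)
  f <- withr::local_tempfile()
  writeTimeSeries(sim$data, f)
  back <- readTimeSeries(f)
  expect_equal(nSeries(back), 5L)
  for (s in 1:5) {
    printed <- matrix(as.numeric(formatC(seriesValues(sim$data, s),
                                         digits = 6, format = "g")), 10, 20)
    expect_equal(unname(seriesValues(back, s)), printed)
  }
})
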