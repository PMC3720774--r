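#' Construct an ExpressionSeries
#'
#' @param values numeric matrix, genes x time points.
#' @param geneNames gene identifiers; defaults to the row names of `values`.
#' @param timePoints strictly increasing time stamps; defaults to 0, 1, ...
#' @param replicates optional list of technical-replicate matrices of the
#'   same shape as `values`.
#' @return An \linkS4class{ExpressionSeries}.
#' @export
ExpressionSeries <- function(values, geneNames = rownames(values),
                             timePoints = seq_len(ncol(values)) - 1,
                             replicates = list()) {
  values <- as.matrix(values)
  if (is.null(geneNames)) geneNames <- paste0("G", seq_len(nrow(values)))
  dimnames(values) <- list(geneNames, NULL)
  new("ExpressionSeries", geneNames = as.character(geneNames),
      timePoints = as.numeric(timePoints), values = values,
      replicates = lapply(replicates, as.matrix))
}

#' Construct a TimeSeriesSet
#'
#' @param series list of \linkS4class{ExpressionSeries} sharing gene names.
#' @param networkId free-text label.
#' @return A \linkS4class{TimeSeriesSet}.
#' @export
TimeSeriesSet <- function(series, networkId = "network") {
  if (is(series, "ExpressionSeries")) series <- list(series)
  new("TimeSeriesSet", series = series, networkId = as.character(networkId))
}

#' Construct a GoldStandard
#'
#' @param edges two-column character matrix or data.frame (regulator,
#'   target) of true edges.
#' @param universe all gene identifiers.
#' @return A \linkS4class{GoldStandard}.
#' @export
GoldStandard <- function(edges, universe) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(character(), ncol = 2L)
  storage.mode(edges) <- "character"
  colnames(edges) <- c("regulator", "target")
  new("GoldStandard", edges = edges, universe = as.character(universe))
}

# Parse one block of time-series lines (header + numeric body).
.parseBlock <- function(lines, lineNos, path, expectGenes = NULL) {
  splitTab <- function(x) strsplit(x, "\t", fixed = TRUE)[[1L]]
  header <- splitTab(lines[1L])
  body <- lines
  bodyNos <- lineNos
  if (toupper(header[1L]) == "TIME") {
    genes <- header[-1L]
    body <- lines[-1L]
    bodyNos <- lineNos[-1L]
  } else if (!is.null(expectGenes)) {
    # block without a repeated header: reuse the first block's genes
    genes <- expectGenes
  } else {
    stopData("parse error in '", path, "' line ", lineNos[1L],
             ": expected header starting with 'Time'")
  }
  if (!is.null(expectGenes) && !identical(genes, expectGenes))
    stopData("inconsistent gene headers in '", path, "' line ", lineNos[1L],
             ": blocks must list the same genes in the same order")
  if (!length(body))
    stopData("parse error in '", path, "': block at line ", lineNos[1L],
             " has no data rows")
  ncols <- length(genes) + 1L
  rows <- lapply(seq_along(body), function(i) {
    f <- splitTab(body[i])
    if (length(f) != ncols)
      stopData("parse error in '", path, "' line ", bodyNos[i], ": expected ",
               ncols, " tab-separated fields, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stopData("parse error in '", path, "' line ", bodyNos[i],
               ": non-numeric value '", f[which(is.na(v))[1L]], "'")
    v
  })
  m <- do.call(rbind, rows)
  ExpressionSeries(t(m[, -1L, drop = FALSE]), geneNames = genes,
                   timePoints = m[, 1L])
}

#' Read DREAM4-style time-series tables
#'
#' Reads tab-separated time-series files whose header row is
#' `Time<TAB>gene1<TAB>...` with one row per time point. A single file may
#' contain several series separated by exactly one blank line (the DREAM4
#' distribution layout), each block optionally repeating the header;
#' alternatively one file per series may be given. Gene order is taken from
#' the first header and must be identical across blocks and files.
#'
#' @param paths one or more file paths.
#' @param networkId label stored on the returned set; defaults to the first
#'   file name.
#' @return A \linkS4class{TimeSeriesSet} with one
#'   \linkS4class{ExpressionSeries} per block/file.
#' @export
readTimeSeries <- function(paths, networkId = NULL) {
  stopifnot(length(paths) >= 1L)
  allSeries <- list()
  genes <- NULL
  for (path in paths) {
    if (!file.exists(path)) stopData("file not found: '", path, "'")
    lines <- readLines(path)
    blank <- !nzchar(trimws(lines))
    # trailing/leading blank lines are tolerated; interior single blanks split
    idx <- which(!blank)
    if (!length(idx)) stopData("parse error in '", path, "': empty file")
    grp <- cumsum(blank)[idx]
    for (g in unique(grp)) {
      sel <- idx[grp == g]
      es <- .parseBlock(lines[sel], sel, path, expectGenes = genes)
      if (is.null(genes)) genes <- es@geneNames
      allSeries[[length(allSeries) + 1L]] <- es
    }
  }
  if (is.null(networkId)) networkId <- basename(paths[1L])
  TimeSeriesSet(allSeries, networkId = networkId)
}

#' Write a TimeSeriesSet as a DREAM4-style table
#'
#' Writes all series into one tab-separated file, blocks separated by one
#' blank line, each block carrying the `Time` header. Values are printed
#' with 6 significant digits. Technical replicates are written as further
#' blocks following their series.
#'
#' @param x a \linkS4class{TimeSeriesSet}.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeTimeSeries <- function(x, path) {
  stopifnot(is(x, "TimeSeriesSet"))
  con <- file(path, "w")
  on.exit(close(con))
  first <- TRUE
  for (s in x@series) {
    for (m in c(list(s@values), s@replicates)) {
      if (!first) writeLines("", con)
      first <- FALSE
      writeLines(paste(c("Time", s@geneNames), collapse = "\t"), con)
      body <- vapply(seq_along(s@timePoints), function(t) {
        paste(c(fmtNum(s@timePoints[t]), fmtNum(m[, t])), collapse = "\t")
      }, "")
      writeLines(body, con)
    }
  }
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Reads a headerless tab-separated file with columns regulator, target,
#' label (0 or 1). Pairs labelled 1 are true edges; every other ordered pair
#' of distinct genes in the universe is a negative.
#'
#' @param path file path.
#' @param geneUniverse character vector of all gene identifiers
#'   (case-sensitive).
#' @return A \linkS4class{GoldStandard}.
#' @export
readGoldStandard <- function(path, geneUniverse) {
  if (!file.exists(path)) stopData("file not found: '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GoldStandard(NULL, geneUniverse))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stopData("parse error in '", path, "' line ", bad[1L],
             ": expected 3 tab-separated fields")
  m <- do.call(rbind, fields)
  lab <- m[, 3L]
  if (!all(lab %in% c("0", "1")))
    stopData("parse error in '", path, "': labels must be 0 or 1")
  unknown <- setdiff(unique(c(m[, 1L], m[, 2L])), geneUniverse)
  if (length(unknown))
    stopData("unknown gene name(s) in '", path, "': ",
             paste(unknown, collapse = ", "))
  key <- paste(m[, 1L], m[, 2L], sep = "\r")
  contradictory <- unique(key[duplicated(key)])
  for (k in contradictory) {
    if (length(unique(lab[key == k])) > 1L)
      stopData("contradictory duplicate lines in '", path, "' for pair ",
               sub("\r", " -> ", k, fixed = TRUE))
  }
  pos <- m[lab == "1", , drop = FALSE]
  if (nrow(pos) && any(pos[, 1L] == pos[, 2L]))
    stopData("self-edge labelled true in '", path, "': ",
             pos[pos[, 1L] == pos[, 2L], 1L][1L])
  pos <- pos[!duplicated(paste(pos[, 1L], pos[, 2L], sep = "\r")), ,
             drop = FALSE]
  GoldStandard(pos[, 1:2, drop = FALSE], geneUniverse)
}

#' Write a ranked edge list
#'
#' Writes the DREAM-submission-style headerless tab-separated file
#' `regulator<TAB>target<TAB>score` in descending absolute-score order.
#' Scores are printed with 6 significant digits.
#'
#' @param table an \linkS4class{EdgeScoreTable}.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeEdgeRanking <- function(table, path) {
  stopifnot(is(table, "EdgeScoreTable"))
  e <- table@entries
  if (!nrow(e)) stopData("refusing to write an empty edge ranking")
  writeLines(paste(e$regulator, e$target, fmtNum(e$score), sep = "\t"), path)
  invisible(path)
}

#' Read a ranked edge list
#'
#' Inverse of [writeEdgeRanking()]: rows are kept in file order, which for a
#' written ranking reproduces the ranking order exactly.
#'
#' @param path file path.
#' @return An \linkS4class{EdgeScoreTable} (cluster-score matrix unset).
#' @export
readEdgeRanking <- function(path) {
  if (!file.exists(path)) stopData("file not found: '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopData("empty edge ranking file: '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stopData("parse error in '", path, "' line ", bad[1L],
             ": expected 3 tab-separated fields")
  m <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score)) stopData("parse error in '", path, "': non-numeric score")
  new("EdgeScoreTable",
      entries = data.frame(regulator = m[, 1L], target = m[, 2L],
                           score = score, stringsAsFactors = FALSE),
      bestK = NA_integer_, clusterScores = matrix(numeric(), 0L, 0L))
}
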