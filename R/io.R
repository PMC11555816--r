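#' Read / write expression TSV
#'
#' Tab-delimited dialect: first column gene id, header row of numeric times;
#' empty cells or \code{NA} mean missing.
#'
#' @param path file path.
#' @return [readExpressionTSV()] returns an \linkS4class{ExpressionSeries}.
#' @name expression-io
NULL

#' @rdname expression-io
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  times <- as.numeric(colnames(df)[-1])
  if (anyNA(times)) stop("header must be numeric times")
  ExpressionSeries(m, times, genes)
}

#' @rdname expression-io
#' @param es an \linkS4class{ExpressionSeries} or
#'   \linkS4class{DiscreteSeries} to write.
#' @export
writeExpressionTSV <- function(es, path) {
  m <- assay(es, 1)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("gene", as.character(timePoints(es)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname expression-io
#' @export
readDiscreteTSV <- function(path) {
  es <- readExpressionTSV(path)
  DiscreteSeries(exprValues(es), timePoints(es), geneIds(es))
}

#' Read / write network edge-list TSV
#'
#' Columns: \code{source}, \code{target}, \code{status}, \code{intervals}
#' (comma-joined interval indices, possibly empty). An optional header-less
#' two-column file is accepted as a prior edge list by [readPriorTSV()].
#'
#' @param path file path.
#' @param nodes optional full node set (defaults to the genes present in the
#'   edge list).
#' @name network-io
NULL

#' @rdname network-io
#' @export
readNetworkTSV <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (is.null(df$status)) df$status <- "unconfirmed"
  if (is.null(df$intervals)) df$intervals <- ""
  df$intervals[is.na(df$intervals)] <- ""
  if (is.null(nodes)) nodes <- unique(c(df$source, df$target))
  RegNetwork(nodes, df)
}

#' @rdname network-io
#' @param net a \linkS4class{RegNetwork} to write.
#' @export
writeNetworkTSV <- function(net, path) {
  utils::write.table(edges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
readPriorTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    stop("prior edge list needs 'source' and 'target' columns")
  df[, c("source", "target")]
}

#' Read / write a segmentation as JSON
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param path file path.
#' @name segmentation-io
NULL

#' @rdname segmentation-io
#' @export
writeSegmentationJSON <- function(seg, path) {
  jsonlite::write_json(list(boundaries = seg@boundaries, alpha = seg@alpha,
                            window = seg@window, test = seg@test),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname segmentation-io
#' @export
readSegmentationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Segmentation(x$boundaries, x$alpha %||% NA_real_, x$window %||% NA_real_,
               x$test %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sensitivity ranking as JSON
#'
#' @param sr a \linkS4class{SensitivityRanking}.
#' @param path file path.
#' @export
writeRankingJSON <- function(sr, path) {
  jsonlite::write_json(list(baseline_entropy = sr@baseline,
                            scores = as.list(sr@scores),
                            ranking = sr@ranking),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an error report as JSON
#'
#' @param er an \linkS4class{ErrorReport}.
#' @param path file path.
#' @export
writeErrorReportJSON <- function(er, path) {
  jsonlite::write_json(list(network_error = er@network,
                            per_gene = as.list(er@perGene),
                            n_draws = er@nDraws, seed = er@seed,
                            joint = er@joint),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
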