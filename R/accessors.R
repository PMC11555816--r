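#' Construct an ExpressionSeries
#'
#' @param values numeric matrix, genes x timepoints. \code{NA} marks a
#'   missing observation.
#' @param times numeric vector of strictly increasing sampling times
#'   (minutes), one per column.
#' @param geneIds character gene identifiers; defaults to
#'   \code{rownames(values)}.
#' @return An \linkS4class{ExpressionSeries}.
#' @examples
#' es <- ExpressionSeries(matrix(rnorm(8), 2, 4,
#'                               dimnames = list(c("A", "B"), NULL)),
#'                        times = c(0, 10, 20, 30))
#' exprValues(es)
#' @export
ExpressionSeries <- function(values, times, geneIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(geneIds))
    geneIds <- paste0("G", seq_len(nrow(values)))
  stopifnot(length(geneIds) == nrow(values),
            length(times) == ncol(values))
  if (ncol(values) < 2)
    stop("an ExpressionSeries needs at least two timepoints")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-missing values must be finite")
  rownames(values) <- geneIds
  colnames(values) <- as.character(times)
  new("ExpressionSeries",
      SummarizedExperiment(assays = list(exprs = values),
                           colData = DataFrame(time = as.numeric(times))))
}

#' Construct a DiscreteSeries
#'
#' @param states integer matrix with entries in \{1, 2, 3\}.
#' @param times,geneIds as in [ExpressionSeries()].
#' @return A \linkS4class{DiscreteSeries}.
#' @export
DiscreteSeries <- function(states, times, geneIds = rownames(states)) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!all(states %in% 1:3))
    stop("discrete states must lie in {1, 2, 3}")
  if (is.null(geneIds))
    geneIds <- paste0("G", seq_len(nrow(states)))
  rownames(states) <- geneIds
  colnames(states) <- as.character(times)
  new("DiscreteSeries",
      SummarizedExperiment(assays = list(states = states),
                           colData = DataFrame(time = as.numeric(times))))
}

#' Accessors for expression containers
#'
#' \code{exprValues} returns the expression assay, \code{states} the discrete
#' state assay, \code{timePoints} the sampling times, \code{geneIds} the gene
#' identifiers and \code{missingMask} the logical matrix of missing entries.
#'
#' @param x an \linkS4class{ExpressionSeries} or
#'   \linkS4class{DiscreteSeries}.
#' @return A matrix or vector as described.
#' @name series-accessors
NULL

#' @rdname series-accessors
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @rdname series-accessors
#' @export
states <- function(x) assay(x, "states")

#' @rdname series-accessors
#' @export
timePoints <- function(x) colData(x)$time

#' @rdname series-accessors
#' @export
geneIds <- function(x) rownames(x)

#' @rdname series-accessors
#' @export
missingMask <- function(x) is.na(assay(x, 1))

#' Construct a Segmentation from explicit boundaries
#'
#' @param boundaries strictly increasing numeric boundary times.
#' @param alpha,window,test metadata describing how the segmentation was
#'   obtained (stored verbatim).
#' @return A \linkS4class{Segmentation}.
#' @export
Segmentation <- function(boundaries, alpha = NA_real_, window = NA_real_,
                         test = NA_character_) {
  new("Segmentation", boundaries = as.numeric(boundaries),
      alpha = alpha, window = window, test = test)
}

#' Segmentation accessors
#'
#' \code{boundaries} returns the interval boundary times, \code{nIntervals}
#' the number of intervals, and \code{intervalTable} a data.frame of
#' start/end times.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @name segmentation-accessors
NULL

#' @rdname segmentation-accessors
#' @export
boundaries <- function(seg) seg@boundaries

#' @rdname segmentation-accessors
#' @export
nIntervals <- function(seg) length(seg@boundaries) - 1L

#' @rdname segmentation-accessors
#' @export
intervalTable <- function(seg) {
  b <- seg@boundaries
  data.frame(interval = seq_len(length(b) - 1L),
             start = b[-length(b)], end = b[-1])
}

# column indices of the observations falling in interval k
# (half-open [t_{k-1}, t_k), last interval closed)
.intervalColumns <- function(seg, times) {
  b <- seg@boundaries
  m <- length(b) - 1L
  lapply(seq_len(m), function(k) {
    if (k < m) which(times >= b[k] & times < b[k + 1])
    else       which(times >= b[k] & times <= b[k + 1])
  })
}

#' Construct a RegNetwork
#'
#' @param nodes character gene identifiers.
#' @param edges data.frame with columns \code{source} and \code{target};
#'   optional \code{status} (default \code{"unconfirmed"}) and
#'   \code{intervals} (default \code{""}). May have zero rows.
#' @param metadata optional list of auxiliary data.
#' @return A \linkS4class{RegNetwork}.
#' @examples
#' net <- RegNetwork(c("A", "B", "C"),
#'                   data.frame(source = "A", target = "B"))
#' edges(net)
#' @export
RegNetwork <- function(nodes, edges = NULL, metadata = list()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        status = character(), intervals = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$status)) edges$status <- "unconfirmed"
    if (is.null(edges$intervals)) edges$intervals <- ""
    edges <- edges[, c("source", "target", "status", "intervals")]
    edges$intervals <- as.character(edges$intervals)
    rownames(edges) <- NULL
  }
  new("RegNetwork", nodes = as.character(nodes), edges = edges,
      metadata = metadata)
}

#' RegNetwork accessors
#'
#' \code{nodes} returns the gene set, \code{edges} the edge table,
#' \code{edgeCount} the number of edges, and \code{edgeStatus} the status
#' column. \code{netMetadata} returns the auxiliary metadata list (e.g. the
#' screening report attached by [screenEdges()]).
#'
#' @param net a \linkS4class{RegNetwork}.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
nodes <- function(net) net@nodes

#' @rdname network-accessors
#' @export
edges <- function(net) net@edges

#' @rdname network-accessors
#' @export
edgeCount <- function(net) nrow(net@edges)

#' @rdname network-accessors
#' @export
edgeStatus <- function(net) net@edges$status

#' @rdname network-accessors
#' @export
netMetadata <- function(net) net@metadata

# undirected adjacency matrix of the edge set (neighbourhood view used by
# the entropy calculations)
.undirectedAdjacency <- function(net) {
  n <- length(net@nodes)
  a <- matrix(FALSE, n, n, dimnames = list(net@nodes, net@nodes))
  e <- net@edges
  if (nrow(e)) {
    i <- match(e$source, net@nodes)
    j <- match(e$target, net@nodes)
    a[cbind(i, j)] <- TRUE
    a[cbind(j, i)] <- TRUE
  }
  a
}

#' SensitivityRanking accessors
#'
#' @param x a \linkS4class{SensitivityRanking}.
#' @name ranking-accessors
NULL

#' @rdname ranking-accessors
#' @export
sensitivity <- function(x) x@scores

#' @rdname ranking-accessors
#' @export
ranking <- function(x) x@ranking

#' @rdname ranking-accessors
#' @export
baselineEntropy <- function(x) x@baseline

setMethod("show", "ExpressionSeries", function(object) {
  cat(sprintf("ExpressionSeries: %d genes x %d timepoints (%g-%g min), %d missing\n",
              nrow(object), ncol(object), min(timePoints(object)),
              max(timePoints(object)), sum(missingMask(object))))
})

setMethod("show", "DiscreteSeries", function(object) {
  cat(sprintf("DiscreteSeries: %d genes x %d timepoints, states {1,2,3}\n",
              nrow(object), ncol(object)))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d intervals, boundaries [%s] (alpha=%s, window=%s, test=%s)\n",
              nIntervals(object),
              paste(object@boundaries, collapse = ", "),
              format(object@alpha), format(object@window), object@test))
})

setMethod("show", "RegNetwork", function(object) {
  s <- table(factor(object@edges$status, levels = .EDGE_STATUSES))
  cat(sprintf("RegNetwork: %d nodes, %d edges (%s)\n",
              length(object@nodes), nrow(object@edges),
              paste(sprintf("%s: %d", names(s), s), collapse = ", ")))
})

setMethod("show", "SensitivityRanking", function(object) {
  cat(sprintf("SensitivityRanking: baseline entropy %.4f; top: %s\n",
              object@baseline,
              paste(utils::head(object@ranking, 3), collapse = " > ")))
})

setMethod("show", "PLSModel", function(object) {
  np <- rowSums(object@coefficients != 0)
  cat(sprintf("PLSModel: %d genes, %d with parents, ncomp=%d\n",
              length(object@nodes), sum(np > 0), as.integer(object@ncomp)))
})

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf("ErrorReport: network error %.4f (%d draws, %s, seed %s)\n",
              object@network, as.integer(object@nDraws), object@joint,
              format(object@seed)))
})
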