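#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionSeries: a gene-by-timepoint expression matrix
#'
#' Container for a real-valued genes x timepoints expression time series.
#' It extends \linkS4class{SummarizedExperiment} with a single assay
#' \code{"exprs"}; sampling times (minutes) live in \code{colData()$time} and
#' missing observations are stored as \code{NA} in the assay. Rows are genes,
#' columns are timepoints.
#'
#' Validity requires at least two timepoints, strictly increasing times, and
#' finite values wherever the entry is not missing.
#'
#' @seealso [ExpressionSeries()], [DiscreteSeries-class]
#' @name ExpressionSeries-class
#' @exportClass ExpressionSeries
setClass("ExpressionSeries", contains = "SummarizedExperiment")

#' DiscreteSeries: three-level discretised expression states
#'
#' Same shape as \linkS4class{ExpressionSeries} but the single assay
#' \code{"states"} holds integer expression states in \{1, 2, 3\}
#' (1 = repressed, 2 = baseline, 3 = induced under the symmetric rule).
#'
#' @seealso [discretizeSeries()], [ExpressionSeries-class]
#' @name DiscreteSeries-class
#' @exportClass DiscreteSeries
setClass("DiscreteSeries", contains = "SummarizedExperiment")

#' Segmentation: stationary plateau intervals of a time series
#'
#' Ordered boundaries \code{t_0 < t_1 < ... < t_m} covering the full series;
#' interval \code{k} is \code{[t_{k-1}, t_k)} with the last interval closed
#' on the right. Produced by [segmentSeries()].
#'
#' @slot boundaries numeric, strictly increasing; first/last equal the series
#'   start/end.
#' @slot alpha significance level used by the merge test.
#' @slot window base window width in minutes.
#' @slot test character, the distribution-equality test used
#'   (\code{"ks"} or \code{"wilcox"}) and its pooling mode.
#' @name Segmentation-class
#' @exportClass Segmentation
setClass("Segmentation",
  representation(boundaries = "numeric", alpha = "numeric",
                 window = "numeric", test = "character"))

setValidity("Segmentation", function(object) {
  b <- object@boundaries
  if (length(b) < 2) return("need at least two boundaries")
  if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
  TRUE
})

.EDGE_STATUSES <- c("confirmed", "unconfirmed", "candidate-added")

#' RegNetwork: a directed gene regulatory network
#'
#' Directed graph over a fixed gene set. Edges carry a status
#' (\code{confirmed} when supported by the prior edge list,
#' \code{unconfirmed} when inferred only, \code{candidate-added} when
#' (re-)admitted by the entropy screen) and a provenance string listing the
#' stationary intervals that contributed the edge. Per-interval networks are
#' acyclic by construction of the K2 search; the union across intervals may
#' contain cycles.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{status}, \code{intervals} (comma-joined interval indices, possibly
#'   empty).
#' @slot metadata list of auxiliary information (e.g. the screening report).
#' @seealso [RegNetwork()], [k2Search()], [unionNetwork()], [screenEdges()]
#' @name RegNetwork-class
#' @exportClass RegNetwork
setClass("RegNetwork",
  representation(nodes = "character", edges = "data.frame",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("RegNetwork", function(object) {
  e <- object@edges
  need <- c("source", "target", "status", "intervals")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) return("duplicated node ids")
  if (nrow(e)) {
    if (!all(e$source %in% object@nodes) || !all(e$target %in% object@nodes))
      return("edge endpoints must be listed in nodes")
    if (any(e$source == e$target)) return("self-loops are not allowed")
    if (!all(e$status %in% .EDGE_STATUSES))
      return(sprintf("edge status must be one of %s",
                     paste(.EDGE_STATUSES, collapse = ", ")))
    if (anyDuplicated(paste(e$source, e$target)))
      return("duplicated edges")
  }
  TRUE
})

#' SensitivityRanking: entropy-drop scores per gene
#'
#' Result of [sensitivityScores()]: for each gene, the decrease in total
#' network entropy when the gene and its incident edges are deleted. Larger
#' scores mark more sensitive (vital) nodes.
#'
#' @slot scores named numeric, one entropy drop per gene.
#' @slot ranking character, genes sorted by decreasing score (ties broken by
#'   original gene order).
#' @slot baseline numeric, total entropy of the intact network.
#' @name SensitivityRanking-class
#' @exportClass SensitivityRanking
setClass("SensitivityRanking",
  representation(scores = "numeric", ranking = "character",
                 baseline = "numeric"))

#' PLSModel: per-gene linear models restricted to network parents
#'
#' Fitted by [fitPLS()]. For each gene with parents the model is a partial
#' least squares regression of the gene's series on its parents' series;
#' coefficients of non-parents are exactly zero. Parentless genes use the
#' constant (training-mean) model. Marginal normal parameters (mean, sd) of
#' every gene and the empirical covariance are stored for simulation.
#'
#' @slot nodes gene identifiers.
#' @slot coefficients genes x genes matrix; row i holds the coefficients of
#'   gene i's model (zero for non-parents).
#' @slot intercepts named numeric intercept per gene.
#' @slot mu,sigma named numeric: fitted marginal normal mean / sd per gene.
#' @slot covariance empirical gene covariance matrix (for joint draws).
#' @slot ncomp number of PLS components requested.
#' @name PLSModel-class
#' @exportClass PLSModel
setClass("PLSModel",
  representation(nodes = "character", coefficients = "matrix",
                 intercepts = "numeric", mu = "numeric", sigma = "numeric",
                 covariance = "matrix", ncomp = "numeric"))

setValidity("PLSModel", function(object) {
  n <- length(object@nodes)
  if (!all(dim(object@coefficients) == c(n, n)))
    return("coefficients must be a genes x genes matrix")
  if (any(object@sigma <= 0)) return("fitted sd must be positive")
  TRUE
})

#' ErrorReport: simulation-based network prediction error
#'
#' Result of [simulateError()]: per-gene mean relative prediction error over
#' simulated draws and the network-level mean over genes that have parents.
#'
#' @slot perGene named numeric mean relative error per gene.
#' @slot network numeric, mean over genes with at least one parent.
#' @slot nDraws number of simulated samples.
#' @slot seed RNG seed used.
#' @slot joint character, \code{"independent"} or \code{"mvnorm"} draws.
#' @name ErrorReport-class
#' @exportClass ErrorReport
setClass("ErrorReport",
  representation(perGene = "numeric", network = "numeric",
                 nDraws = "numeric", seed = "numeric", joint = "character"))
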