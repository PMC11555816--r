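#' Correlation with automatic Pearson/Spearman switch
#'
#' Runs a Shapiro-Wilk normality test on each series at level \code{alpha};
#' if both pass, the Pearson correlation is returned, otherwise the Spearman
#' rank correlation. The entropy calculations downstream use the absolute
#' value, so the sign is informational only.
#'
#' @param x,y numeric series of equal length (>= 3), non-constant.
#' @param alpha significance level of the normality test (default 0.05).
#' @return List with \code{coefficient} (signed, in [-1, 1]) and \code{kind}
#'   (\code{"pearson"} or \code{"spearman"}).
#' @export
corrWithNormalitySwitch <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("series 'x' is constant")
  if (stats::sd(y) == 0) stop("series 'y' is constant")
  normal <- function(v) stats::shapiro.test(v)$p.value > alpha
  kind <- if (normal(x) && normal(y)) "pearson" else "spearman"
  list(coefficient = suppressWarnings(stats::cor(x, y, method = kind)),
       kind = kind)
}

#' Pairwise correlation matrix of an expression series
#'
#' Applies [corrWithNormalitySwitch()] to every gene pair. The result is a
#' symmetric matrix with unit diagonal and a \code{"kind"} attribute holding
#' the method used per pair.
#'
#' @param es a complete \linkS4class{ExpressionSeries}.
#' @param alpha normality-test level (default 0.05).
#' @return Numeric gene x gene correlation matrix with attribute
#'   \code{"kind"}.
#' @export
pairwiseCorrelation <- function(es, alpha = 0.05) {
  v <- exprValues(es)
  if (anyNA(v)) stop("correlations require a complete matrix; impute first")
  g <- rownames(v)
  n <- length(g)
  cm <- diag(1, n)
  kind <- matrix("", n, n, dimnames = list(g, g))
  dimnames(cm) <- list(g, g)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cc <- corrWithNormalitySwitch(v[i, ], v[j, ], alpha)
    cm[i, j] <- cm[j, i] <- cc$coefficient
    kind[i, j] <- kind[j, i] <- cc$kind
  }
  attr(cm, "kind") <- kind
  cm
}

# resolve a correlation matrix for entropy computations
.resolveCorr <- function(net, expr, corr, alpha = 0.05) {
  if (is.null(corr)) {
    if (is.null(expr)) stop("supply either 'expr' or 'corr'")
    corr <- pairwiseCorrelation(expr, alpha)
  }
  nd <- nodes(net)
  if (is.null(dimnames(corr)[[1]]) || !all(nd %in% rownames(corr)))
    stop("correlation matrix must be named by the network's genes")
  corr[nd, nd, drop = FALSE]
}

# entropies of all nodes given an undirected logical adjacency and the
# absolute correlation matrix (rows/cols aligned); the p_ij normalise the
# absolute correlations over each node's neighbours
.entropiesFromAdj <- function(adj, acorr, logBase = exp(1)) {
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ])
    if (!length(nb)) return(0)
    w <- acorr[i, nb]
    sw <- sum(w)
    if (sw == 0) return(0)
    p <- w[w > 0] / sw
    -sum(p * log(p, base = logBase))
  }, numeric(1))
}

#' Node entropy from neighbour correlations
#'
#' Shannon entropy of the distribution obtained by normalising the absolute
#' correlations between a gene and its network neighbours (in- and out-edges
#' viewed undirected):
#' \deqn{H_i = -\sum_j p_{ij} \log p_{ij}, \qquad
#'       p_{ij} = \frac{|corr(k_i, k_j)|}{\sum_{m \in nb(i)} |corr(k_i, k_m)|}}
#' Isolated nodes, and nodes all of whose neighbour correlations are zero,
#' have entropy 0 by convention.
#'
#' @param net a \linkS4class{RegNetwork}.
#' @param expr a complete \linkS4class{ExpressionSeries} (used to compute
#'   correlations unless \code{corr} is given).
#' @param node gene identifier.
#' @param corr optional precomputed correlation matrix (genes x genes, named)
#'   overriding \code{expr}.
#' @param logBase base of the logarithm (default natural log, nats).
#' @return Nonnegative entropy; at most \code{log(degree)}.
#' @export
nodeEntropy <- function(net, expr = NULL, node, corr = NULL,
                        logBase = exp(1)) {
  stopifnot(node %in% nodes(net))
  cm <- .resolveCorr(net, expr, corr)
  adj <- .undirectedAdjacency(net)
  h <- .entropiesFromAdj(adj, abs(cm), logBase)
  h[match(node, nodes(net))]
}

#' Total network entropy
#'
#' Sum of [nodeEntropy()] over all nodes. Lower total entropy is read as a
#' more stable (more ordered) network; the edge screen and the sensitivity
#' ranking are both defined in terms of changes of this quantity.
#'
#' @inheritParams nodeEntropy
#' @return Nonnegative total entropy.
#' @export
networkEntropy <- function(net, expr = NULL, corr = NULL, logBase = exp(1)) {
  cm <- .resolveCorr(net, expr, corr)
  adj <- .undirectedAdjacency(net)
  sum(.entropiesFromAdj(adj, abs(cm), logBase))
}
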