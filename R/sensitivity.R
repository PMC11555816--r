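#' Rank genes by the entropy drop under node deletion
#'
#' For the screened network with total entropy \code{c}, each gene \code{i}
#' is deleted in turn together with all its incident edges; the surviving
#' nodes' entropies are recomputed from scratch on the reduced neighbourhood
#' (their \eqn{p_{ij}} renormalise over the remaining neighbours), giving a
#' reduced total \code{d_i}. The sensitivity score is \code{g_i = c - d_i}:
#' the larger the entropy drop, the more vital the node. The ranking sorts
#' \code{g} in decreasing order, breaking ties by the original gene order.
#'
#' @param net a nonempty \linkS4class{RegNetwork}.
#' @param expr a complete \linkS4class{ExpressionSeries}, or supply
#'   \code{corr}.
#' @param corr optional precomputed correlation matrix.
#' @param logBase entropy log base (default natural log).
#' @return A \linkS4class{SensitivityRanking}.
#' @examples
#' # a hub whose removal erases all entropy ranks first
#' net <- RegNetwork(c("H", "L1", "L2", "L3"),
#'   data.frame(source = "H", target = c("L1", "L2", "L3")))
#' cm <- diag(4); cm[cm == 0] <- 0.5
#' dimnames(cm) <- list(nodes(net), nodes(net))
#' sensitivityScores(net, corr = cm)
#' @export
sensitivityScores <- function(net, expr = NULL, corr = NULL,
                              logBase = exp(1)) {
  cm <- .resolveCorr(net, expr, corr)
  acorr <- abs(cm)
  nd <- nodes(net)
  adj <- .undirectedAdjacency(net)
  cTot <- sum(.entropiesFromAdj(adj, acorr, logBase))
  g <- vapply(seq_along(nd), function(i) {
    keep <- setdiff(seq_along(nd), i)
    dTot <- sum(.entropiesFromAdj(adj[keep, keep, drop = FALSE],
                                  acorr[keep, keep, drop = FALSE], logBase))
    cTot - dTot
  }, numeric(1))
  names(g) <- nd
  ord <- order(-g, seq_along(g))
  new("SensitivityRanking", scores = g, ranking = nd[ord], baseline = cTot)
}
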