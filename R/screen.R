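# total entropy of the graph formed by a fixed confirmed edge matrix plus a
# subset of candidate edges, working directly on index matrices for speed
.entropyOfEdgeSet <- function(n, edgeIdx, acorr, logBase) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edgeIdx)) {
    adj[edgeIdx] <- TRUE
    adj[edgeIdx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  sum(.entropiesFromAdj(adj, acorr, logBase))
}

#' Screen unconfirmed edges by network entropy
#'
#' Starting from the confirmed subnetwork, every unconfirmed edge is tried
#' against contexts built from the \emph{other} unconfirmed edges of its
#' group: a context is any nonempty subset of those edges (sizes 1 to group
#' size minus 1, optionally capped by \code{maxContext}). For each context
#' the total network entropy is evaluated with (\code{d}) and without
#' (\code{c}) the edge under test; a \emph{violation} is counted whenever
#' \code{d - c > a}, i.e. the edge destabilises that context by more than
#' the threshold. The edge is admitted (status \code{candidate-added}) when
#' its violation count stays below \code{b}.
#'
#' \code{mode = "literal"} instead reproduces the published pseudocode
#' verbatim: the counter compares \code{c - d > a} and is reset to zero
#' rather than incremented, so every edge is admitted; it is retained only
#' for fidelity.
#'
#' @param net a \linkS4class{RegNetwork} whose edges are labelled
#'   \code{confirmed} / \code{unconfirmed}.
#' @param expr a complete \linkS4class{ExpressionSeries}, or supply
#'   \code{corr}.
#' @param corr optional precomputed correlation matrix.
#' @param a entropy-increase threshold (case study: 0.3).
#' @param b violation-count threshold(s), one per group (case study: 100 for
#'   the 8-edge group, 200 for the 9-edge group).
#' @param groups optional list of integer vectors partitioning the
#'   unconfirmed-edge indices (in edge-table order) into groups; default is
#'   a single group.
#' @param maxContext cap on the context size (default \code{Inf}); groups
#'   with more than 20 unconfirmed edges require a finite cap.
#' @param mode \code{"strict"} (default, corrected semantics) or
#'   \code{"literal"}.
#' @param logBase entropy log base.
#' @param alpha normality-test level for the correlation switch.
#' @return A \linkS4class{RegNetwork} of the confirmed edges plus the
#'   admitted edges; \code{netMetadata(x)$screening} holds the per-edge
#'   report (group, context count, violations, decision).
#' @export
screenEdges <- function(net, expr = NULL, corr = NULL, a = 0.3, b = 1L,
                        groups = NULL, maxContext = Inf,
                        mode = c("strict", "literal"), logBase = exp(1),
                        alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(b >= 1))
  cm <- .resolveCorr(net, expr, corr, alpha)
  acorr <- abs(cm)
  nd <- nodes(net)
  n <- length(nd)
  e <- edges(net)
  confIdx <- which(e$status == "confirmed")
  uncIdx <- which(e$status != "confirmed")
  if (is.null(groups)) {
    groups <- if (length(uncIdx)) list(seq_along(uncIdx)) else list()
  }
  if (length(groups)) {
    flat <- sort(unlist(groups))
    if (!identical(flat, seq_along(uncIdx)))
      stop("'groups' must partition the unconfirmed edges 1..",
           length(uncIdx))
  }
  b <- rep_len(b, length(groups))
  if (any(lengths(groups) > 20) && !is.finite(maxContext))
    stop("a group has more than 20 unconfirmed edges; set a finite ",
         "'maxContext' to avoid combinatorial blowup")
  edgeMat <- cbind(match(e$source, nd), match(e$target, nd))
  confMat <- edgeMat[confIdx, , drop = FALSE]
  nu <- length(uncIdx)
  report <- data.frame(source = e$source[uncIdx], target = e$target[uncIdx],
                       group = rep(NA_integer_, nu), contexts = rep(0L, nu),
                       violations = rep(0L, nu), accepted = rep(NA, nu),
                       stringsAsFactors = FALSE)
  accepted <- logical(length(uncIdx))
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    for (ei in grp) {
      others <- setdiff(grp, ei)
      sizes <- seq_len(min(length(others), maxContext))
      viol <- 0L; ctx <- 0L
      for (m in sizes) {
        combs <- utils::combn(others, m)
        for (col in seq_len(ncol(combs))) {
          sub <- combs[, col]
          base <- rbind(confMat, edgeMat[uncIdx[sub], , drop = FALSE])
          cEnt <- .entropyOfEdgeSet(n, base, acorr, logBase)
          dEnt <- .entropyOfEdgeSet(
            n, rbind(base, edgeMat[uncIdx[ei], , drop = FALSE]),
            acorr, logBase)
          ctx <- ctx + 1L
          if (mode == "strict") {
            if (dEnt - cEnt > a) viol <- viol + 1L
          } else {
            # published form: reset on c - d > a, never increment
            if (cEnt - dEnt > a) viol <- 0L
          }
        }
      }
      accepted[ei] <- viol < b[gi]
      report$group[ei] <- gi
      report$contexts[ei] <- ctx
      report$violations[ei] <- viol
      report$accepted[ei] <- accepted[ei]
    }
  }
  keep <- e[confIdx, , drop = FALSE]
  add <- e[uncIdx[accepted], , drop = FALSE]
  if (nrow(add)) add$status <- "candidate-added"
  out <- rbind(keep, add)
  rownames(out) <- NULL
  RegNetwork(nd, out, metadata = list(
    screening = report,
    config = list(a = a, b = b, maxContext = maxContext, mode = mode)))
}
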