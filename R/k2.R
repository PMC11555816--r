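#' Log K2 (Cooper-Herskovits) score of a parent set
#'
#' Bayesian marginal-likelihood score of one gene's parent set under a
#' uniform Dirichlet prior, computed from the contingency counts
#' \eqn{N_{ijk}} (observations with the target in state \eqn{k} while the
#' parents show configuration \eqn{j}):
#' \deqn{score(i, \pi_i) = \prod_j \frac{(r-1)!}{(N_{ij}+r-1)!}
#'       \prod_k N_{ijk}!}
#' Only parent configurations actually observed contribute (unobserved
#' configurations multiply by 1). The value is returned as a natural log;
#' all arithmetic uses log-factorials, since raw factorials overflow at
#' modest sample sizes.
#'
#' @param target integer vector of target states (values in \code{1:r}).
#' @param parents integer matrix of parent states, observations in rows
#'   (one column per parent), or \code{NULL} for the empty parent set.
#' @param r number of target states (2 or 3; default 3 to match the
#'   three-level discretisation).
#' @return log score (0 for zero observations, by the empty-product
#'   convention).
#' @examples
#' k2Score(c(1L, 1L), r = 2)            # log(1/3)
#' k2Score(c(1L, 2L), r = 2)            # log(1/6)
#' @export
k2Score <- function(target, parents = NULL, r = 3L) {
  if (length(target) == 0) return(0)
  stopifnot(all(target >= 1), all(target <= r))
  if (is.null(parents)) {
    cfg <- rep(1L, length(target))
  } else {
    parents <- as.matrix(parents)
    stopifnot(nrow(parents) == length(target))
    cfg <- as.integer(interaction(as.data.frame(parents), drop = TRUE))
  }
  total <- 0
  for (j in unique(cfg)) {
    tk <- target[cfg == j]
    nk <- tabulate(tk, nbins = r)
    nij <- sum(nk)
    total <- total + lfactorial(r - 1) - lfactorial(nij + r - 1) +
      sum(lfactorial(nk))
  }
  total
}

#' Greedy K2 structure search on one stationary interval
#'
#' For each gene, taken in the supplied ordering, greedily adds the
#' predecessor (earlier in the ordering) whose addition most increases the
#' gene's [k2Score()], stopping when no candidate increases the score or
#' when \code{maxParents} parents have been added. Because parents are drawn
#' only from ordering-predecessors, the result is acyclic by construction.
#' Ties are broken in favour of the candidate with the lowest original gene
#' index, so runs are deterministic.
#'
#' @param d a \linkS4class{DiscreteSeries} (typically restricted to one
#'   stationary interval's columns).
#' @param ordering character permutation of the gene ids giving the assumed
#'   upstream-to-downstream order; default is the row order of \code{d}.
#' @param maxParents maximum number of parents per gene (default 3).
#' @param r number of states per gene (default 3).
#' @return A \linkS4class{RegNetwork} with all edges \code{unconfirmed}.
#' @export
k2Search <- function(d, ordering = geneIds(d), maxParents = 3L, r = 3L) {
  st <- states(d)
  gid <- rownames(st)
  stopifnot(setequal(ordering, gid))
  maxParents <- min(maxParents, length(gid) - 1L)
  src <- character(0); tgt <- character(0)
  for (pos in seq_along(ordering)) {
    g <- ordering[pos]
    pred <- ordering[seq_len(pos - 1L)]
    parents <- character(0)
    current <- k2Score(st[g, ], NULL, r)
    while (length(parents) < maxParents) {
      cand <- setdiff(pred, parents)
      if (!length(cand)) break
      sc <- vapply(cand, function(p)
        k2Score(st[g, ], t(st[c(parents, p), , drop = FALSE]), r), numeric(1))
      best <- max(sc)
      if (best <= current) break
      # lowest original gene index wins ties
      pick <- cand[sc == best]
      pick <- pick[which.min(match(pick, gid))]
      parents <- c(parents, pick)
      current <- best
    }
    if (length(parents)) {
      src <- c(src, parents)
      tgt <- c(tgt, rep(g, length(parents)))
    }
  }
  RegNetwork(gid, if (length(src))
    data.frame(source = src, target = tgt, status = "unconfirmed",
               intervals = "", stringsAsFactors = FALSE))
}

#' Learn one network per stationary interval
#'
#' Runs [k2Search()] on the columns of each interval of a segmentation and
#' stamps each edge with the interval index it came from.
#'
#' @param d a \linkS4class{DiscreteSeries} over the full series.
#' @param seg a \linkS4class{Segmentation}.
#' @inheritParams k2Search
#' @return List of \linkS4class{RegNetwork}, one per interval.
#' @export
learnIntervalNetworks <- function(d, seg, ordering = geneIds(d),
                                  maxParents = 3L, r = 3L) {
  cols <- .intervalColumns(seg, timePoints(d))
  lapply(seq_along(cols), function(k) {
    if (!length(cols[[k]])) stop(sprintf("interval %d has no observations", k))
    net <- k2Search(d[, cols[[k]]], ordering, maxParents, r)
    if (edgeCount(net)) net@edges$intervals <- as.character(k)
    net
  })
}

#' Union of interval networks with prior annotation
#'
#' Collapses a list of per-interval networks into one summary network: the
#' edge set is the union over intervals, each edge's provenance records the
#' contributing interval indices, and an edge is \code{confirmed} when it
#' appears in the prior edge list, \code{unconfirmed} otherwise. The union
#' may contain directed cycles even though each interval network is a DAG.
#'
#' @param nets list of \linkS4class{RegNetwork} sharing one node set.
#' @param prior optional data.frame of confirmed edges with columns
#'   \code{source} and \code{target}; referencing unknown genes is an error.
#' @return A \linkS4class{RegNetwork}.
#' @export
unionNetwork <- function(nets, prior = NULL) {
  stopifnot(length(nets) >= 1)
  nd <- nodes(nets[[1]])
  for (n in nets) stopifnot(setequal(nodes(n), nd))
  if (!is.null(prior)) {
    prior <- as.data.frame(prior)
    bad <- setdiff(unique(c(prior$source, prior$target)), nd)
    if (length(bad))
      stop(sprintf("prior references unknown genes: %s",
                   paste(bad, collapse = ", ")))
  }
  all <- do.call(rbind, lapply(seq_along(nets), function(k) {
    e <- edges(nets[[k]])
    if (nrow(e) && !nzchar(e$intervals[1])) e$intervals <- as.character(k)
    e
  }))
  if (is.null(all) || nrow(all) == 0) return(RegNetwork(nd))
  key <- paste(all$source, all$target, sep = "\r")
  agg <- lapply(split(seq_len(nrow(all)), key)[unique(key)], function(i) {
    iv <- sort(unique(as.integer(unlist(
      strsplit(all$intervals[i], ",", fixed = TRUE)))))
    data.frame(source = all$source[i[1]], target = all$target[i[1]],
               status = "unconfirmed",
               intervals = paste(iv, collapse = ","),
               stringsAsFactors = FALSE)
  })
  e <- do.call(rbind, agg)
  rownames(e) <- NULL
  if (!is.null(prior) && nrow(prior)) {
    pk <- paste(prior$source, prior$target, sep = "\r")
    e$status[paste(e$source, e$target, sep = "\r") %in% pk] <- "confirmed"
  }
  # stable order: by source then target position in the node list
  e <- e[order(match(e$source, nd), match(e$target, nd)), ]
  rownames(e) <- NULL
  RegNetwork(nd, e)
}
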