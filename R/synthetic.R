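#' Configuration for the synthetic piecewise-stationary generator
#'
#' Describes a seeded synthetic dataset with known ground truth: a short
#' multivariate series (default mimics an 8-gene, 17-timepoint cell-cycle
#' course sampled every 10 minutes from 0 to 160) split into stationary
#' segments, each carrying its own linear regulatory DAG. Within a segment,
#' parentless genes draw independent \code{N(segmentMeans[s], 1)} values and
#' every child is the weighted sum of its parents plus \code{N(0, noiseSd)}
#' noise; segment changes shift the baseline means, which is what the
#' segmentation stage detects. A \code{missingRate} fraction of entries is
#' masked uniformly at random.
#'
#' If \code{networks} is \code{NULL}, each segment receives a random DAG of
#' \code{nEdges} forward edges with respect to the gene order (so the truth
#' is consistent with the default K2 ordering), all with weight
#' \code{weight}.
#'
#' @param nGenes number of genes (default 8).
#' @param times sampling times in minutes (default \code{seq(0, 160, 10)}).
#' @param boundaries interior segment boundaries on the time axis (default
#'   none: a single stationary segment).
#' @param networks optional list (one per segment) of data.frames with
#'   columns \code{source}, \code{target}, \code{weight} naming genes
#'   \code{G1..Gn}; must be acyclic.
#' @param nEdges number of random forward edges per segment when
#'   \code{networks} is NULL (default 3).
#' @param weight edge weight for random networks (default 0.9).
#' @param noiseSd child noise standard deviation (default 0.1).
#' @param segmentMeans baseline mean per segment for parentless genes
#'   (default alternating \code{0, 2, 0, 2, ...}).
#' @param missingRate fraction of entries masked at random, in [0, 1)
#'   (default 0).
#' @param seed integer seed; the generator is a pure function of the
#'   configuration.
#' @return A list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nGenes = 8L, times = seq(0, 160, 10),
                        boundaries = numeric(0), networks = NULL,
                        nEdges = 3L, weight = 0.9, noiseSd = 0.1,
                        segmentMeans = NULL, missingRate = 0, seed = 1L) {
  stopifnot(missingRate >= 0, missingRate < 1, nGenes >= 2,
            all(boundaries > min(times)), all(boundaries < max(times)))
  nSeg <- length(boundaries) + 1L
  if (is.null(segmentMeans))
    segmentMeans <- rep(c(0, 2), length.out = nSeg)
  stopifnot(length(segmentMeans) == nSeg)
  structure(list(nGenes = as.integer(nGenes), times = as.numeric(times),
                 boundaries = as.numeric(boundaries), networks = networks,
                 nEdges = as.integer(nEdges), weight = weight,
                 noiseSd = noiseSd, segmentMeans = segmentMeans,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "SynthConfig")
}

# random forward DAG over genes 1..n (edges i -> j with i < j)
.randomForwardDag <- function(nGenes, nEdges, weight) {
  if (nEdges < 1)
    return(data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  all <- which(upper.tri(matrix(0, nGenes, nGenes)), arr.ind = TRUE)
  pick <- all[sample.int(nrow(all), min(nEdges, nrow(all))), , drop = FALSE]
  data.frame(source = paste0("G", pick[, 1]), target = paste0("G", pick[, 2]),
             weight = weight, stringsAsFactors = FALSE)
}

.checkAcyclic <- function(edgeDf, genes) {
  if (!nrow(edgeDf)) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edgeDf[, c("source", "target")],
                                     vertices = genes, directed = TRUE)
  if (!igraph::is_dag(g)) stop("truth network contains a directed cycle")
  invisible(TRUE)
}

#' Generate a seeded synthetic dataset with known truth
#'
#' @param cfg a [synthConfig()] object.
#' @return List with \code{expr} (an \linkS4class{ExpressionSeries}, missing
#'   entries masked as NA) and \code{truth} (list of
#'   \linkS4class{RegNetwork}, one per segment; edge weights kept in
#'   \code{netMetadata(net)$weights}).
#' @examples
#' d <- generateSynthetic(synthConfig(seed = 7))
#' d$expr
#' @export
generateSynthetic <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  genes <- paste0("G", seq_len(cfg$nGenes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  nSeg <- length(cfg$boundaries) + 1L
  nets <- cfg$networks
  if (is.null(nets))
    nets <- replicate(nSeg,
                      .randomForwardDag(cfg$nGenes, cfg$nEdges, cfg$weight),
                      simplify = FALSE)
  stopifnot(length(nets) == nSeg)
  for (e in nets) .checkAcyclic(e, genes)
  segOf <- findInterval(cfg$times,
                        c(min(cfg$times), cfg$boundaries), rightmost.closed = FALSE)
  v <- matrix(NA_real_, cfg$nGenes, length(cfg$times),
              dimnames = list(genes, NULL))
  truth <- vector("list", nSeg)
  for (s in seq_len(nSeg)) {
    cols <- which(segOf == s)
    e <- nets[[s]]
    g <- igraph::graph_from_data_frame(
      if (nrow(e)) e[, c("source", "target")] else
        data.frame(source = character(), target = character()),
      vertices = genes, directed = TRUE)
    ord <- names(igraph::topo_sort(g))
    for (gn in ord) {
      pa <- e[e$target == gn, , drop = FALSE]
      if (!nrow(pa)) {
        v[gn, cols] <- stats::rnorm(length(cols), cfg$segmentMeans[s], 1)
      } else {
        base <- colSums(v[pa$source, cols, drop = FALSE] * pa$weight)
        v[gn, cols] <- base + stats::rnorm(length(cols), 0, cfg$noiseSd)
      }
    }
    truth[[s]] <- RegNetwork(genes,
      if (nrow(e)) data.frame(source = e$source, target = e$target,
                              status = "unconfirmed",
                              intervals = as.character(s),
                              stringsAsFactors = FALSE),
      metadata = list(weights = e$weight))
  }
  if (cfg$missingRate > 0) {
    mask <- stats::runif(length(v)) < cfg$missingRate
    # never mask a whole gene below 2 observations
    v[matrix(mask, nrow(v))] <- NA_real_
  }
  list(expr = ExpressionSeries(v, cfg$times), truth = truth)
}

# direction-sensitive precision/recall of predicted vs true edges
.prf <- function(predicted, truth) {
  pk <- paste(predicted$source, predicted$target)
  tk <- paste(truth$source, truth$target)
  tp <- sum(pk %in% tk)
  prec <- if (length(pk) == 0) 1 else tp / length(pk)
  rec <- if (length(tk) == 0) 1 else tp / length(tk)
  c(precision = prec, recall = rec)
}

#' Edge-recovery report for the full pipeline on synthetic data
#'
#' Generates a dataset from \code{cfg}, runs
#' filter/impute/normalise/discretise, segments the series, learns one K2
#' network per interval, and scores the learned edges against the known
#' truth per true segment (direction-sensitive). Learned intervals are
#' assigned to the true segment containing their midpoint; the edges of all
#' intervals assigned to a segment are pooled (union) before scoring.
#'
#' @param cfg a [synthConfig()] object.
#' @param window,alpha segmentation parameters.
#' @param maxParents,r,ordering K2 parameters (ordering defaults to the
#'   generator's gene order).
#' @param discretize discretisation mode.
#' @return data.frame with one row per true segment (\code{precision},
#'   \code{recall}) plus attribute \code{"segmentation"}.
#' @export
recoveryReport <- function(cfg, window = 50, alpha = 0.01, maxParents = 3L,
                           r = 3L, ordering = NULL,
                           discretize = c("symmetric", "literal")) {
  discretize <- match.arg(discretize)
  d <- generateSynthetic(cfg)
  es <- d$expr
  es <- filterByMissingRate(es, 1)
  es <- imputeMissing(es)
  es <- normalizeSeries(es)
  ds <- discretizeSeries(es, discretize)
  seg <- segmentSeries(es, window = window, alpha = alpha)
  if (is.null(ordering)) ordering <- geneIds(ds)
  nets <- learnIntervalNetworks(ds, seg, ordering, maxParents, r)
  tb <- intervalTable(seg)
  mid <- (tb$start + tb$end) / 2
  segBreaks <- c(min(cfg$times), cfg$boundaries, max(cfg$times))
  segOf <- findInterval(mid, segBreaks, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_along(d$truth), function(s) {
    pool <- nets[segOf == s]
    pred <- if (length(pool)) unique(do.call(rbind, lapply(pool, function(n)
      edges(n)[, c("source", "target")])))
    else data.frame(source = character(), target = character())
    p <- .prf(pred, edges(d$truth[[s]]))
    data.frame(segment = s, nPredicted = nrow(pred),
               nTrue = edgeCount(d$truth[[s]]),
               precision = p["precision"], recall = p["recall"])
  }))
  rownames(out) <- NULL
  attr(out, "segmentation") <- seg
  out
}
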