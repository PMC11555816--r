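#' Drop genes with too many missing observations
#'
#' Keeps exactly the genes whose fraction of missing timepoints is at most
#' \code{maxRate}, preserving the original order. The case-study screen uses
#' a 15\% ceiling.
#'
#' @param es an \linkS4class{ExpressionSeries}.
#' @param maxRate maximum tolerated missing fraction per gene, in [0, 1].
#' @return The filtered \linkS4class{ExpressionSeries}.
#' @export
filterByMissingRate <- function(es, maxRate = 0.15) {
  stopifnot(is(es, "ExpressionSeries"), maxRate >= 0, maxRate <= 1)
  rate <- rowMeans(missingMask(es))
  keep <- rate <= maxRate
  if (!any(keep))
    stop("all genes exceed the missing-rate threshold: empty matrix")
  es[keep, ]
}

#' Impute missing observations by cubic spline interpolation
#'
#' Interior missing values of each gene are filled by piecewise-cubic spline
#' interpolation over time (FMM end conditions, which reproduce data lying
#' exactly on a cubic polynomial); genes with fewer than four observed points
#' fall back to linear interpolation. Missing values outside the observed
#' time range (masked endpoints) take the nearest observed value. Observed
#' entries are never changed.
#'
#' @param es an \linkS4class{ExpressionSeries}.
#' @return An \linkS4class{ExpressionSeries} with no missing values.
#' @export
imputeMissing <- function(es) {
  stopifnot(is(es, "ExpressionSeries"))
  v <- exprValues(es)
  tm <- timePoints(es)
  for (g in seq_len(nrow(v))) {
    y <- v[g, ]
    obs <- which(!is.na(y))
    if (length(obs) == length(y)) next
    if (length(obs) < 2)
      stop(sprintf("gene %s has fewer than 2 observed points; cannot impute",
                   rownames(v)[g]))
    miss <- which(is.na(y))
    lo <- min(tm[obs]); hi <- max(tm[obs])
    inner <- miss[tm[miss] > lo & tm[miss] < hi]
    outer <- setdiff(miss, inner)
    if (length(inner)) {
      y[inner] <- if (length(obs) >= 4)
        stats::spline(tm[obs], y[obs], xout = tm[inner], method = "fmm")$y
      else
        stats::approx(tm[obs], y[obs], xout = tm[inner])$y
    }
    if (length(outer)) {
      nearest <- vapply(outer, function(i) obs[which.min(abs(tm[obs] - tm[i]))],
                        integer(1))
      y[outer] <- y[nearest]
    }
    v[g, ] <- y
  }
  ExpressionSeries(v, tm)
}

#' Normalise expression per gene
#'
#' Default is the per-gene z-score (mean 0, sample standard deviation 1);
#' \code{"minmax"} rescales each gene to [0, 1]. Requires a complete matrix
#' (run [imputeMissing()] first).
#'
#' @param es an \linkS4class{ExpressionSeries} without missing values.
#' @param method \code{"zscore"} (default) or \code{"minmax"}.
#' @return A normalised \linkS4class{ExpressionSeries}.
#' @export
normalizeSeries <- function(es, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  v <- exprValues(es)
  if (anyNA(v)) stop("normalise requires a complete matrix; impute first")
  s <- apply(v, 1, stats::sd)
  rng <- apply(v, 1, function(x) diff(range(x)))
  flat <- if (method == "zscore") s == 0 else rng == 0
  if (any(flat))
    stop(sprintf("constant gene(s): %s",
                 paste(rownames(v)[flat], collapse = ", ")))
  v <- if (method == "zscore") (v - rowMeans(v)) / s
       else (v - apply(v, 1, min)) / rng
  ExpressionSeries(v, timePoints(es))
}

#' Discretise expression into three states
#'
#' With per-gene mean \code{mu} and sample standard deviation \code{s}, the
#' default \code{"symmetric"} rule assigns state 3 above \code{mu + s},
#' state 1 below \code{mu - s} and state 2 in between. The \code{"literal"}
#' rule keeps the asymmetric published form: state 3 above \code{mu + s},
#' state 2 only at exact equality with \code{mu + s}, and state 1 below it
#' (so state 2 occurs with probability zero on continuous data).
#'
#' @param es an \linkS4class{ExpressionSeries} without missing values.
#' @param mode \code{"symmetric"} (default) or \code{"literal"}.
#' @return A \linkS4class{DiscreteSeries}.
#' @export
discretizeSeries <- function(es, mode = c("symmetric", "literal")) {
  mode <- match.arg(mode)
  v <- exprValues(es)
  if (anyNA(v)) stop("discretise requires a complete matrix; impute first")
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  up <- mu + s
  dn <- mu - s
  st <- matrix(1L, nrow(v), ncol(v))
  if (mode == "symmetric") {
    st[v >= dn & v <= up] <- 2L
    st[v > up] <- 3L
  } else {
    st[v == up] <- 2L
    st[v > up] <- 3L
  }
  DiscreteSeries(st, timePoints(es), geneIds(es))
}
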