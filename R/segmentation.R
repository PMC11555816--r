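#' Plateau ratio statistic (RB)
#'
#' Ratio of a gene's mean absolute deviation within an interval \code{[s, t]}
#' to its mean absolute deviation over the whole series. Values near 0
#' indicate a plateau (the gene barely fluctuates inside the interval
#' relative to its overall variability); the full series gives exactly 1.
#'
#' @param values numeric series of one gene (no missing values).
#' @param times sampling times, same length; defaults to indices.
#' @param s,t interval limits (inclusive, on the time axis).
#' @return Nonnegative ratio of interval to whole-series mean absolute
#'   deviation.
#' @examples
#' rbStatistic(c(1, 2, 3, 4), s = 1, t = 2)  # 0.5
#' @export
rbStatistic <- function(values, times = seq_along(values), s = min(times),
                        t = max(times)) {
  stopifnot(length(values) == length(times), !anyNA(values))
  idx <- times >= s & times <= t
  if (!any(idx)) stop("interval [s, t] contains no observations")
  madWhole <- mean(abs(values - mean(values)))
  if (madWhole == 0)
    stop("whole series is constant: RB statistic undefined")
  madInt <- mean(abs(values[idx] - mean(values[idx])))
  madInt / madWhole
}

#' RB profile of a segmentation
#'
#' Evaluates [rbStatistic()] for every gene on every interval of a
#' segmentation; reported alongside the segmentation for diagnostics.
#'
#' @param es a complete \linkS4class{ExpressionSeries}.
#' @param seg a \linkS4class{Segmentation}.
#' @return Matrix genes x intervals of RB values.
#' @export
rbProfile <- function(es, seg) {
  v <- exprValues(es)
  tm <- timePoints(es)
  cols <- .intervalColumns(seg, tm)
  out <- sapply(seq_along(cols), function(k)
    apply(v, 1, function(y) {
      madW <- mean(abs(y - mean(y)))
      if (madW == 0) return(NA_real_)
      yy <- y[cols[[k]]]
      mean(abs(yy - mean(yy))) / madW
    }))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v), paste0("I", seq_along(cols))))
  out
}

# two-sample distribution-equality p-value between the observations of two
# intervals; x, y are genes x columns matrices
.mergePValue <- function(x, y, test, pooling) {
  one <- function(a, b) {
    if (test == "ks")
      suppressWarnings(stats::ks.test(a, b))$p.value
    else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
  }
  if (pooling == "pooled") one(as.vector(x), as.vector(y))
  else min(vapply(seq_len(nrow(x)), function(g) one(x[g, ], y[g, ]),
                  numeric(1)))
}

#' Segment a multivariate series into stationary plateau intervals
#'
#' The time axis is cut into consecutive base windows of width \code{window}
#' minutes (the last window absorbs any remainder and is closed on the
#' right). Adjacent intervals are then merged whenever a two-sample
#' distribution-equality test between their observations does not reject at
#' level \code{alpha}; a merged interval is immediately compared with the
#' next window, and left-to-right passes repeat until no adjacent pair
#' merges.
#'
#' By default the test compares the values of \emph{all} genes pooled
#' (the stationarity requirement applies to every gene jointly, and short
#' series leave only a couple of points per gene per window);
#' \code{pooling = "per-gene"} instead requires that no single gene rejects.
#'
#' @param es a complete \linkS4class{ExpressionSeries} (impute first).
#' @param window base window width in minutes (default 20).
#' @param alpha significance level of the merge test (default 0.01).
#' @param test \code{"ks"} (two-sample Kolmogorov-Smirnov, default) or
#'   \code{"wilcox"} (Mann-Whitney).
#' @param pooling \code{"pooled"} (default) or \code{"per-gene"}.
#' @param base optional explicit base boundary vector overriding the window
#'   grid (used e.g. to re-segment an existing segmentation).
#' @return A \linkS4class{Segmentation}.
#' @examples
#' set.seed(1)
#' es <- ExpressionSeries(matrix(rnorm(8 * 17), 8, 17), seq(0, 160, 10))
#' segmentSeries(es, window = 20, alpha = 0.01)
#' @export
segmentSeries <- function(es, window = 20, alpha = 0.01,
                          test = c("ks", "wilcox"),
                          pooling = c("pooled", "per-gene"), base = NULL) {
  test <- match.arg(test)
  pooling <- match.arg(pooling)
  stopifnot(alpha > 0, alpha < 1)
  v <- exprValues(es)
  if (anyNA(v)) stop("segmentation requires a complete matrix; impute first")
  tm <- timePoints(es)
  if (is.null(base)) {
    if (max(tm) - min(tm) < window)
      stop("series shorter than one base window")
    base <- seq(min(tm), max(tm), by = window)
    if (base[length(base)] < max(tm)) {
      # absorb the remainder into the last window
      base[length(base)] <- max(tm)
    }
  }
  b <- as.numeric(base)
  seg <- Segmentation(b, alpha, window, sprintf("%s/%s", test, pooling))
  cols <- .intervalColumns(seg, tm)
  if (any(lengths(cols) < 2))
    stop("every base window must span at least 2 observations")
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(cols)) {
      p <- .mergePValue(v[, cols[[i]], drop = FALSE],
                        v[, cols[[i + 1]], drop = FALSE], test, pooling)
      if (p >= alpha) {
        cols[[i]] <- c(cols[[i]], cols[[i + 1]])
        cols[[i + 1]] <- NULL
        b <- b[-(i + 1)]
        merged <- TRUE
        # the merged interval is immediately compared with the next window
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  Segmentation(b, alpha, window, sprintf("%s/%s", test, pooling))
}
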