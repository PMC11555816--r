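# parents (sources of in-edges) per gene in a directed network
.parentList <- function(net) {
  e <- edges(net)
  sapply(nodes(net), function(g) unique(e$source[e$target == g]),
         simplify = FALSE)
}

# linear coefficients of a fitted mixOmics PLS model, recovered exactly by
# predicting at the coordinate basis (the model is linear in X)
.plsCoef <- function(X, y, ncomp) {
  Y <- matrix(y, ncol = 1, dimnames = list(NULL, ".y"))
  fit <- mixOmics::pls(X, Y, ncomp = ncomp, mode = "regression")
  basis <- rbind(0, diag(ncol(X)))
  colnames(basis) <- colnames(X)
  pred <- predict(fit, basis)$predict[, 1, ncomp]
  list(intercept = pred[1], beta = pred[-1] - pred[1])
}

#' Fit per-gene PLS models restricted to network parents
#'
#' Each gene with at least one parent in the network is modelled as a linear
#' combination of its parents' expression series,
#' \eqn{x_i(t) = \beta_0 + \sum_{j \in pa(i)} \beta_j x_j(t)},
#' fitted by partial least squares regression with
#' \code{min(nComponents, #parents)} components; coefficients of non-parents
#' are exactly zero. Parentless genes use the constant training-mean model.
#' With a single parent, one-component PLS coincides with simple least
#' squares, which is used directly in that case. Marginal normal parameters
#' (sample mean and sd per gene) and the empirical gene covariance are
#' stored for the simulation step.
#'
#' @param expr a complete \linkS4class{ExpressionSeries}.
#' @param net a \linkS4class{RegNetwork} over the same genes.
#' @param nComponents number of PLS components (default 2, capped at the
#'   parent count).
#' @return A \linkS4class{PLSModel}.
#' @export
fitPLS <- function(expr, net, nComponents = 2L) {
  v <- exprValues(expr)
  if (anyNA(v)) stop("PLS fitting requires a complete matrix; impute first")
  nd <- nodes(net)
  stopifnot(all(nd %in% rownames(v)))
  v <- v[nd, , drop = FALSE]
  pa <- .parentList(net)
  beta <- matrix(0, length(nd), length(nd), dimnames = list(nd, nd))
  b0 <- stats::setNames(rowMeans(v), nd)
  for (g in nd) {
    p <- pa[[g]]
    if (!length(p)) next
    if (ncol(v) < length(p) + 1)
      stop(sprintf("gene %s: need at least %d timepoints for %d parents",
                   g, length(p) + 1, length(p)))
    flat <- p[apply(v[p, , drop = FALSE], 1, stats::sd) == 0]
    if (length(flat))
      stop(sprintf("constant parent series for gene %s: %s", g,
                   paste(flat, collapse = ", ")))
    y <- v[g, ]
    if (length(p) == 1) {
      # PLS1 with one predictor and one component == simple least squares
      x <- v[p, ]
      slope <- stats::cov(x, y) / stats::var(x)
      beta[g, p] <- slope
      b0[g] <- mean(y) - slope * mean(x)
    } else {
      X <- t(v[p, , drop = FALSE])
      cf <- .plsCoef(X, y, ncomp = min(nComponents, length(p)))
      beta[g, p] <- cf$beta
      b0[g] <- cf$intercept
    }
  }
  sds <- apply(v, 1, stats::sd)
  if (any(sds <= 0))
    stop(sprintf("constant gene(s): %s",
                 paste(nd[sds <= 0], collapse = ", ")))
  new("PLSModel", nodes = nd, coefficients = beta, intercepts = b0,
      mu = stats::setNames(rowMeans(v), nd), sigma = stats::setNames(sds, nd),
      covariance = stats::cov(t(v)), ncomp = as.numeric(nComponents))
}

# predict every gene from a draws x genes matrix; parentless genes predict
# their training mean (intercept)
.predictGenes <- function(model, draws) {
  t(model@coefficients %*% t(draws)) +
    matrix(model@intercepts, nrow(draws), length(model@nodes), byrow = TRUE)
}

#' Simulate expression and score a network's prediction error
#'
#' Draws \code{nDraws} joint expression samples from the fitted normal
#' parameters -- independently per gene by default, or from a multivariate
#' normal with the empirical covariance when \code{joint = "mvnorm"} -- then
#' predicts every gene from its parents through the PLS model. The per-gene
#' relative error is the mean over draws of
#' \eqn{|pred - drawn| / (|drawn| + \epsilon)} and the network error is the
#' mean over genes that have parents. A fixed seed gives a bit-identical
#' report.
#'
#' Note that independent draws discard the dependence the model was fitted
#' on, so they measure only the spread a network's predictions add; ranking
#' competing networks by how well they exploit gene-gene dependence requires
#' \code{joint = "mvnorm"} (or [predictionError()] on observed data).
#'
#' @param model a \linkS4class{PLSModel}.
#' @param net the \linkS4class{RegNetwork} the model was fitted to (used for
#'   the genes-with-parents average).
#' @param nDraws number of simulated samples (>= 1).
#' @param seed integer RNG seed.
#' @param joint \code{"independent"} (default) or \code{"mvnorm"}.
#' @param eps guard added to the denominator of the relative error
#'   (default 1e-8).
#' @return An \linkS4class{ErrorReport}.
#' @export
simulateError <- function(model, net, nDraws = 1000L, seed = 1L,
                          joint = c("independent", "mvnorm"), eps = 1e-8) {
  joint <- match.arg(joint)
  if (nDraws < 1) stop("nDraws must be at least 1")
  nd <- model@nodes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- if (joint == "independent") {
    sapply(nd, function(g) stats::rnorm(nDraws, model@mu[g], model@sigma[g]))
  } else {
    MASS::mvrnorm(nDraws, mu = model@mu, Sigma = model@covariance)
  }
  draws <- matrix(draws, nrow = nDraws, dimnames = list(NULL, nd))
  pred <- .predictGenes(model, draws)
  rel <- colMeans(abs(pred - draws) / (abs(draws) + eps))
  hasPa <- lengths(.parentList(net))[nd] > 0
  new("ErrorReport", perGene = rel,
      network = if (any(hasPa)) mean(rel[hasPa]) else NA_real_,
      nDraws = as.numeric(nDraws), seed = as.numeric(seed), joint = joint)
}

#' Prediction error on the observed series
#'
#' Real-data counterpart of [simulateError()]: evaluates the fitted model on
#' the training expression matrix itself.
#'
#' @inheritParams simulateError
#' @param expr the complete \linkS4class{ExpressionSeries}.
#' @return An \linkS4class{ErrorReport} (with \code{nDraws} = number of
#'   timepoints and \code{joint = "observed"}).
#' @export
predictionError <- function(model, net, expr, eps = 1e-8) {
  v <- exprValues(expr)[model@nodes, , drop = FALSE]
  draws <- t(v)
  pred <- .predictGenes(model, draws)
  rel <- colMeans(abs(pred - draws) / (abs(draws) + eps))
  hasPa <- lengths(.parentList(net))[model@nodes] > 0
  new("ErrorReport", perGene = rel,
      network = if (any(hasPa)) mean(rel[hasPa]) else NA_real_,
      nDraws = ncol(v), seed = NA_real_, joint = "observed")
}

#' Per-gene normality screen
#'
#' Shapiro-Wilk test of each gene's expression series; genes with p-value
#' above \code{alpha} are flagged as consistent with normality (and hence
#' eligible for Pearson correlations downstream).
#'
#' @param expr a complete \linkS4class{ExpressionSeries} with >= 3
#'   timepoints.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns \code{gene}, \code{p.value}, \code{pass}.
#' @export
normalityScreen <- function(expr, alpha = 0.05) {
  v <- exprValues(expr)
  if (anyNA(v)) stop("normality screen requires a complete matrix")
  if (ncol(v) < 3) stop("need at least 3 timepoints")
  p <- apply(v, 1, function(x) {
    if (stats::sd(x) == 0)
      stop("constant series: normality test undefined")
    stats::shapiro.test(x)$p.value
  })
  data.frame(gene = rownames(v), p.value = as.numeric(p), pass = p > alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
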