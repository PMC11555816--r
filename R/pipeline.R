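.PIPELINE_KEYS <- c("input", "prior", "outdir", "maxMissing", "discretize",
                    "window", "alpha", "test", "pooling", "ordering",
                    "maxParents", "r", "a", "b", "groupSizes", "maxContext",
                    "screenMode", "logBase", "normalityAlpha", "draws",
                    "joint", "seed", "synthetic")

.defaultPipelineConfig <- function() {
  list(maxMissing = 0.15, discretize = "symmetric", window = 20, alpha = 0.01,
       test = "ks", pooling = "pooled", ordering = NULL, maxParents = 3,
       r = 3, a = 0.3, b = 1, groupSizes = NULL, maxContext = Inf,
       screenMode = "strict", logBase = exp(1), normalityAlpha = 0.05,
       draws = 1000, joint = "independent", seed = 1)
}

# "8:100,9:200" or list form -> list(groups = list(idx...), b = c(...))
.resolveGroups <- function(groupSizes, b, nUnconfirmed) {
  if (is.null(groupSizes)) return(list(groups = NULL, b = b))
  sizes <- as.integer(groupSizes)
  if (sum(sizes) != nUnconfirmed)
    stop(sprintf("group sizes sum to %d but there are %d unconfirmed edges",
                 sum(sizes), nUnconfirmed))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  list(groups = Map(seq, starts, ends), b = rep_len(b, length(sizes)))
}

#' Run the full dynamic-network-entropy pipeline
#'
#' Executes preprocess (filter, impute, normalise, discretise), plateau
#' segmentation, per-interval K2 learning, union with the prior, entropy
#' screening, sensitivity ranking, and PLS validation, writing every
#' intermediate artifact plus a manifest into \code{outdir}. Configuration
#' is a named list (or a path to a JSON file with the same keys); unknown
#' keys are rejected and all defaults are those of the individual stage
#' functions. A dataset is either read from \code{input} (expression TSV) or
#' generated by the \code{synthetic} sub-configuration (passed to
#' [synthConfig()]).
#'
#' @param config named list or path to a JSON config file. Keys:
#'   \code{input}, \code{prior}, \code{outdir}, \code{maxMissing},
#'   \code{discretize}, \code{window}, \code{alpha}, \code{test},
#'   \code{pooling}, \code{ordering}, \code{maxParents}, \code{r}, \code{a},
#'   \code{b}, \code{groupSizes}, \code{maxContext}, \code{screenMode},
#'   \code{logBase}, \code{normalityAlpha}, \code{draws}, \code{joint},
#'   \code{seed}, \code{synthetic}.
#' @return Invisibly, a list with every stage result (\code{expr},
#'   \code{disc}, \code{seg}, \code{intervalNets}, \code{union},
#'   \code{screened}, \code{ranking}, \code{error}, \code{normality},
#'   \code{manifest}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(fn, name) if (!is.null(outdir))
    fn(file.path(outdir, name))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))

  es <- stage("input", {
    if (!is.null(cfg$input)) readExpressionTSV(cfg$input)
    else if (!is.null(cfg$synthetic)) {
      sc <- do.call(synthConfig, as.list(cfg$synthetic))
      generateSynthetic(sc)$expr
    } else stop("config must provide 'input' or 'synthetic'")
  })
  prior <- if (!is.null(cfg$prior)) stage("prior", readPriorTSV(cfg$prior))

  es <- stage("preprocess", {
    e <- filterByMissingRate(es, cfg$maxMissing)
    imputeMissing(e)
  })
  norm <- stage("normalize", normalizeSeries(es))
  disc <- stage("discretize", discretizeSeries(norm, cfg$discretize))
  emit(function(p) writeExpressionTSV(norm, p), "expr_normalized.tsv")
  emit(function(p) writeExpressionTSV(disc, p), "disc.tsv")

  seg <- stage("segment", segmentSeries(norm, cfg$window, cfg$alpha,
                                        cfg$test, cfg$pooling))
  emit(function(p) writeSegmentationJSON(seg, p), "seg.json")

  ordering <- cfg$ordering %||% geneIds(disc)
  nets <- stage("learn", learnIntervalNetworks(disc, seg, ordering,
                                               cfg$maxParents, cfg$r))
  un <- stage("union", unionNetwork(nets, prior))
  emit(function(p) writeNetworkTSV(un, p), "net_union.tsv")

  normality <- stage("normality", normalityScreen(norm, cfg$normalityAlpha))
  cm <- stage("correlation", pairwiseCorrelation(norm, cfg$normalityAlpha))
  nUnc <- sum(edgeStatus(un) != "confirmed")
  grp <- .resolveGroups(cfg$groupSizes, cfg$b, nUnc)
  screened <- stage("screen", screenEdges(un, corr = cm, a = cfg$a, b = grp$b,
                                          groups = grp$groups,
                                          maxContext = cfg$maxContext,
                                          mode = cfg$screenMode,
                                          logBase = cfg$logBase))
  emit(function(p) writeNetworkTSV(screened, p), "screened.tsv")

  rank <- stage("rank", sensitivityScores(screened, corr = cm,
                                          logBase = cfg$logBase))
  emit(function(p) writeRankingJSON(rank, p), "ranking.json")

  model <- stage("fit", fitPLS(norm, screened))
  err <- stage("validate", simulateError(model, screened, cfg$draws,
                                         cfg$seed, cfg$joint))
  emit(function(p) writeErrorReportJSON(err, p), "error.json")

  manifest <- list(package = "dynent",
                   version = as.character(utils::packageVersion("dynent")),
                   parameters = cfg[setdiff(names(cfg), "outdir")],
                   genes = geneIds(disc),
                   boundaries = boundaries(seg),
                   edgeCounts = list(union = edgeCount(un),
                                     confirmed = sum(edgeStatus(un) == "confirmed"),
                                     screened = edgeCount(screened)),
                   topGene = ranking(rank)[1])
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  invisible(list(expr = norm, disc = disc, seg = seg, intervalNets = nets,
                 union = un, screened = screened, ranking = rank,
                 error = err, normality = normality, manifest = manifest))
}
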