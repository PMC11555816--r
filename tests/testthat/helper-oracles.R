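# Independent oracles and small fixture builders used across the suite.

# Exact Cooper-Herskovits score via plain factorial products (valid for the
# small sample sizes used in tests; independent of the package's
# log-factorial path).
k2ScoreOracle <- function(target, parents = NULL, r = 3L) {
  if (length(target) == 0) return(0)
  key <- if (is.null(parents)) rep("", length(target))
         else apply(as.matrix(parents), 1, paste, collapse = "|")
  s <- 1
  for (j in unique(key)) {
    tk <- target[key == j]
    nk <- vapply(seq_len(r), function(k) sum(tk == k), numeric(1))
    s <- s * factorial(r - 1) / factorial(sum(nk) + r - 1) *
      prod(factorial(nk))
  }
  log(s)
}

# Step-by-step greedy replay using the oracle score; returns the parent set
# chosen for each gene (list named by gene), mirroring the documented
# tie-break (lowest original gene index).
k2GreedyOracle <- function(st, ordering = rownames(st), maxParents = 3L,
                           r = 3L) {
  gid <- rownames(st)
  out <- list()
  for (pos in seq_along(ordering)) {
    g <- ordering[pos]
    pred <- ordering[seq_len(pos - 1L)]
    parents <- character(0)
    current <- k2ScoreOracle(st[g, ], NULL, r)
    repeat {
      if (length(parents) >= maxParents) break
      cand <- setdiff(pred, parents)
      if (!length(cand)) break
      sc <- vapply(cand, function(p)
        k2ScoreOracle(st[g, ], t(st[c(parents, p), , drop = FALSE]), r),
        numeric(1))
      if (max(sc) <= current) break
      pick <- cand[sc == max(sc)]
      pick <- pick[which.min(match(pick, gid))]
      parents <- c(parents, pick)
      current <- max(sc)
    }
    out[[g]] <- parents
  }
  out
}

# parent sets of a learned RegNetwork as a named list
parentSets <- function(net) {
  e <- edges(net)
  sapply(nodes(net), function(g) sort(e$source[e$target == g]),
         simplify = FALSE)
}

# quick series builder
makeSeries <- function(values, times = seq(0, by = 10,
                                           length.out = ncol(values))) {
  ExpressionSeries(values, times)
}

# named correlation matrix from a vector of upper-triangle values
corrMatrix <- function(genes, fill = 0.5) {
  n <- length(genes)
  m <- matrix(fill, n, n, dimnames = list(genes, genes))
  diag(m) <- 1
  m
}

# star network: hub H with nLeaves leaves L1..Lk
starNetwork <- function(nLeaves = 3) {
  leaves <- paste0("L", seq_len(nLeaves))
  RegNetwork(c("H", leaves),
             data.frame(source = "H", target = leaves,
                        stringsAsFactors = FALSE))
}
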