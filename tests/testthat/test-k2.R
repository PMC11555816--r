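test_that("K2 score reproduces the hand-computed factorial values", {
  expect_equal(k2Score(c(1L, 1L), r = 2), log(1 / 3), tolerance = 1e-12)
  expect_equal(k2Score(c(1L, 2L), r = 2), log(1 / 6), tolerance = 1e-12)
  expect_identical(k2Score(integer(0), r = 2), 0)
  expect_equal(k2Score(c(1L, 1L, 2L, 2L), matrix(c(1L, 1L, 2L, 2L)), r = 2),
               log(1 / 9), tolerance = 1e-12)
  # three-state target, two parents
  set.seed(20)
  tg <- sample(1:3, 10, TRUE)
  pa <- matrix(sample(1:3, 20, TRUE), 10, 2)
  expect_equal(k2Score(tg, pa, r = 3), k2ScoreOracle(tg, pa, r = 3),
               tolerance = 1e-9)
})

test_that("greedy search recovers planted deterministic edges and stays empty under independence", {
  planted <- 0
  for (s in 1:20) {
    set.seed(s)
    p <- sample(1:3, 50, TRUE)
    st <- rbind(A = p, B = p, C = sample(1:3, 50, TRUE))
    ds <- DiscreteSeries(st, seq_len(50))
    e <- edges(k2Search(ds, maxParents = 2))
    if (any(e$source == "A" & e$target == "B")) planted <- planted + 1
  }
  expect_equal(planted, 20)
  empty <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    ds <- DiscreteSeries(matrix(sample(1:3, 3 * 200, TRUE), 3, 200),
                         seq_len(200))
    if (edgeCount(k2Search(ds, maxParents = 2)) == 0) empty <- empty + 1
  }
  expect_gte(empty / 20, 0.8)
})

test_that("greedy parent sets match the step-replayed enumeration oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:4, 1)
    st <- matrix(sample(1:3, n * 10, TRUE), n, 10,
                 dimnames = list(paste0("G", 1:n), NULL))
    ds <- DiscreteSeries(st, seq_len(10))
    got <- parentSets(k2Search(ds, maxParents = 2))
    want <- lapply(k2GreedyOracle(st, maxParents = 2), sort)
    expect_identical(got[names(want)], want)
  }
})

test_that("search respects ordering, parent cap and acyclicity", {
  set.seed(22)
  st <- matrix(sample(1:3, 5 * 60, TRUE), 5, 60,
               dimnames = list(paste0("G", 1:5), NULL))
  st[2, ] <- st[1, ]; st[3, ] <- st[1, ]      # strong dependence
  ds <- DiscreteSeries(st, seq_len(60))
  ord <- c("G3", "G1", "G2", "G4", "G5")
  net <- k2Search(ds, ordering = ord, maxParents = 1)
  e <- edges(net)
  pos <- match(ord, ord)
  for (i in seq_len(nrow(e)))
    expect_lt(match(e$source[i], ord), match(e$target[i], ord))
  expect_true(all(table(e$target) <= 1))
  g <- igraph::graph_from_data_frame(e[, 1:2], vertices = nodes(net))
  expect_true(igraph::is_dag(g))
  # output never scores below the empty graph, per gene
  for (gn in nodes(net)) {
    pa <- e$source[e$target == gn]
    if (length(pa))
      expect_gte(k2Score(st[gn, ], t(st[pa, , drop = FALSE])),
                 k2Score(st[gn, ], NULL))
  }
})

test_that("interval learning is per-interval and deterministic", {
  set.seed(23)
  p <- sample(1:3, 40, TRUE)
  st <- rbind(A = p, B = p, C = sample(1:3, 40, TRUE))
  ds <- DiscreteSeries(cbind(st, st), seq_len(80))
  seg1 <- Segmentation(c(1, 80))
  nets1 <- learnIntervalNetworks(ds, seg1)
  expect_length(nets1, 1)
  expect_identical(edges(nets1[[1]])[, 1:2],
                   edges(k2Search(ds))[, 1:2])
  # identical data in two intervals -> identical networks
  seg2 <- Segmentation(c(1, 41, 80))
  nets2 <- learnIntervalNetworks(ds, seg2)
  expect_identical(edges(nets2[[1]])[, 1:2], edges(nets2[[2]])[, 1:2])
  expect_identical(edges(nets2[[1]])$intervals,
                   rep("1", edgeCount(nets2[[1]])))
})

test_that("union merges provenance, applies the prior and is order-invariant", {
  nd <- c("A", "B", "C")
  n1 <- RegNetwork(nd, data.frame(source = "A", target = "B",
                                  status = "unconfirmed", intervals = "1"))
  n2 <- RegNetwork(nd, data.frame(source = c("A", "B"), target = c("B", "C"),
                                  status = "unconfirmed", intervals = "2"))
  u <- unionNetwork(list(n1, n2), prior = data.frame(source = "B",
                                                     target = "C"))
  e <- edges(u)
  expect_identical(nrow(e), 2L)
  expect_identical(e$intervals[e$source == "A"], "1,2")
  expect_identical(e$status[e$source == "B"], "confirmed")
  expect_identical(e$status[e$source == "A"], "unconfirmed")
  # order invariance
  u2 <- unionNetwork(list(n2, n1), prior = data.frame(source = "B",
                                                      target = "C"))
  expect_identical(edges(u2), e)
  # idempotent union; disjoint edges add up
  expect_identical(edges(unionNetwork(list(n1, n1)))[, 1:2],
                   edges(n1)[, 1:2])
  n3 <- RegNetwork(nd, data.frame(source = "C", target = "A",
                                  status = "unconfirmed", intervals = "3"))
  expect_identical(edgeCount(unionNetwork(list(n1, n3))), 2L)
  expect_error(unionNetwork(list(n1), prior = data.frame(source = "Z",
                                                         target = "A")),
               "unknown genes")
})
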