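test_that("noiseless linear relations are recovered exactly", {
  set.seed(60)
  x <- rnorm(20)
  es <- makeSeries(rbind(P = x, C = 2 * x, Z = rnorm(20)), seq_len(20))
  net <- RegNetwork(c("P", "C", "Z"), data.frame(source = "P", target = "C"))
  m <- fitPLS(es, net)
  expect_lt(abs(m@coefficients["C", "P"] - 2), 1e-6)
  err <- predictionError(m, net, es)
  expect_lt(err@network, 1e-6)
  # parentless genes predict their training mean
  expect_identical(m@coefficients["Z", ], c(P = 0, C = 0, Z = 0))
  expect_equal(m@intercepts[["Z"]], mean(exprValues(es)["Z", ]))
})

test_that("two orthogonal parents are both recovered with two components", {
  x1 <- rep(c(1, -1), 10)
  x2 <- rep(c(1, 1, -1, -1), 5)
  es <- makeSeries(rbind(P1 = x1, P2 = x2, C = x1 + x2, Z = rnorm(20)),
                   seq_len(20))
  net <- RegNetwork(c("P1", "P2", "C", "Z"),
                    data.frame(source = c("P1", "P2"), target = "C"))
  m <- fitPLS(es, net, nComponents = 2)
  expect_equal(unname(m@coefficients["C", c("P1", "P2")]), c(1, 1),
               tolerance = 1e-6)
})

test_that("non-parents never influence predictions", {
  set.seed(61)
  v <- matrix(rnorm(4 * 30), 4, 30,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  es <- makeSeries(v, seq_len(30))
  net <- RegNetwork(rownames(v), data.frame(source = "A", target = "B"))
  m <- fitPLS(es, net)
  r1 <- simulateError(m, net, 50, seed = 7)
  # permute a non-parent's series and refit: B's model must be unchanged
  v2 <- v; v2["C", ] <- v["C", sample(30)]
  m2 <- fitPLS(makeSeries(v2, seq_len(30)), net)
  expect_equal(m@coefficients["B", ], m2@coefficients["B", ])
  r2 <- simulateError(m2, net, 50, seed = 7)
  expect_identical(r1@perGene[["B"]], r2@perGene[["B"]])
})

test_that("simulation is bit-identical under a fixed seed and errors on bad draws", {
  set.seed(62)
  es <- makeSeries(matrix(rnorm(3 * 20), 3, 20,
                          dimnames = list(c("A", "B", "C"), NULL)),
                   seq_len(20))
  net <- RegNetwork(c("A", "B", "C"), data.frame(source = "A", target = "B"))
  m <- fitPLS(es, net)
  r1 <- simulateError(m, net, 100, seed = 3)
  r2 <- simulateError(m, net, 100, seed = 3)
  expect_identical(r1@perGene, r2@perGene)
  expect_identical(r1@network, r2@network)
  r3 <- simulateError(m, net, 100, seed = 4)
  expect_false(identical(r1@perGene, r3@perGene))
  expect_error(simulateError(m, net, 0, seed = 1), "nDraws")
  # joint draws are deterministic too
  j1 <- simulateError(m, net, 100, seed = 3, joint = "mvnorm")
  j2 <- simulateError(m, net, 100, seed = 3, joint = "mvnorm")
  expect_identical(j1@perGene, j2@perGene)
})

test_that("relative error is invariant to gene order and errors shrink with noise", {
  set.seed(63)
  # keep the series away from zero so the relative-error denominator is tame
  x <- rnorm(40) + 5
  errs <- sapply(c(1, 0.1, 0.001), function(ns) {
    v <- rbind(P = x, C = 0.9 * x + rnorm(40, 0, ns), Z = rnorm(40))
    es <- makeSeries(v, seq_len(40))
    net <- RegNetwork(rownames(v), data.frame(source = "P", target = "C"))
    predictionError(fitPLS(es, net), net, es)@network
  })
  expect_true(all(diff(errs) < 0))
  # gene order invariance
  v <- rbind(P = x, C = 0.9 * x + rnorm(40, 0, 0.1), Z = rnorm(40))
  es1 <- makeSeries(v, seq_len(40))
  es2 <- makeSeries(v[c("Z", "C", "P"), ], seq_len(40))
  net <- RegNetwork(c("P", "C", "Z"), data.frame(source = "P", target = "C"))
  e1 <- predictionError(fitPLS(es1, net), net, es1)
  e2 <- predictionError(fitPLS(es2, net), net, es2)
  expect_equal(e1@network, e2@network, tolerance = 1e-9)
})

test_that("degenerate parents and constant genes are rejected with names", {
  es <- makeSeries(rbind(P = rep(1, 10), C = rnorm(10), Z = rnorm(10)),
                   seq_len(10))
  net <- RegNetwork(c("P", "C", "Z"), data.frame(source = "P", target = "C"))
  expect_error(fitPLS(es, net), "P")
})

test_that("normality screen has the right level, power and error cases", {
  set.seed(64)
  # level: large-sample standard normal genes pass at about 1 - alpha
  v <- matrix(rnorm(200 * 50), 200, 50)
  scr <- normalityScreen(makeSeries(v, seq_len(50)))
  expect_gt(mean(scr$pass), 0.9)
  expect_lt(mean(scr$pass), 1)
  # power: exponential genes fail nearly always at n = 100
  fails <- 0
  for (s in 1:20) {
    set.seed(s)
    e <- matrix(rexp(2 * 100), 2, 100)
    scr <- normalityScreen(makeSeries(e, seq_len(100)))
    fails <- fails + sum(!scr$pass)
  }
  expect_gte(fails / 40, 0.95)
  expect_error(normalityScreen(makeSeries(rbind(rep(1, 10), rnorm(10)),
                                          seq_len(10))), "constant")
})
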