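test_that("missing-rate filter keeps exactly the genes under the threshold", {
  tm <- seq(0, 160, 10)
  v <- matrix(rnorm(3 * 17), 3, 17, dimnames = list(c("A", "B", "C"), NULL))
  v["B", 1:4] <- NA                       # 4/17 ~ 0.235 missing
  es <- makeSeries(v, tm)
  kept <- filterByMissingRate(es, 0.15)
  expect_identical(geneIds(kept), c("A", "C"))
  # order preserved, all kept at a permissive threshold
  expect_identical(geneIds(filterByMissingRate(es, 0.5)), c("A", "B", "C"))
  v[] <- NA_real_
  v[, 1] <- 1
  expect_error(filterByMissingRate(makeSeries(v, tm), 0.15), "empty matrix")
})

test_that("imputation fills interior gaps on a cubic exactly and never touches observed values", {
  tm <- seq(0, 160, 10)
  poly <- function(t) 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  y <- poly(tm)
  ymask <- y; ymask[9] <- NA
  set.seed(1)
  other <- rnorm(17)
  es <- makeSeries(rbind(A = ymask, B = other), tm)
  imp <- imputeMissing(es)
  expect_false(any(missingMask(imp)))
  expect_lt(abs(exprValues(imp)["A", 9] - poly(tm[9])), 1e-8)
  expect_equal(exprValues(imp)["A", -9], y[-9], ignore_attr = TRUE)
  expect_identical(exprValues(imp)["B", ], exprValues(es)["B", ])
  # no missing values: identity
  expect_identical(exprValues(imputeMissing(imp)), exprValues(imp))
})

test_that("masked endpoints take the nearest observed value", {
  tm <- seq(0, 60, 10)
  y <- c(NA, 3, 5, 7, 9, 11, NA)
  es <- makeSeries(rbind(A = y, B = seq(1, 2, length.out = 7)), tm)
  imp <- imputeMissing(es)
  expect_identical(exprValues(imp)["A", 1], 3)
  expect_identical(exprValues(imp)["A", 7], 11)
})

test_that("genes with too few observations fail loudly, few observations fall back to linear", {
  tm <- seq(0, 40, 10)
  v <- rbind(A = c(1, NA, NA, NA, NA), B = rnorm(5))
  expect_error(imputeMissing(makeSeries(v, tm)), "A")
  # 3 observed points -> linear interpolation
  v2 <- rbind(A = c(0, NA, 2, NA, 4), B = rnorm(5))
  imp <- imputeMissing(makeSeries(v2, tm))
  expect_equal(exprValues(imp)["A", ], c(0, 1, 2, 3, 4),
               ignore_attr = TRUE)
})

test_that("z-score normalisation standardises and is idempotent and affine-invariant", {
  es <- makeSeries(rbind(A = c(1, 2, 3), B = c(10, 20, 30)), c(0, 10, 20))
  nm <- normalizeSeries(es)
  v <- exprValues(nm)
  expect_equal(rowMeans(v), c(A = 0, B = 0))
  expect_equal(apply(v, 1, sd), c(A = 1, B = 1))
  # affine invariance: [10,20,30] normalises identically to [1,2,3]
  expect_equal(v["A", ], v["B", ], ignore_attr = TRUE)
  # idempotence
  expect_equal(exprValues(normalizeSeries(nm)), v, tolerance = 1e-12)
  expect_error(normalizeSeries(makeSeries(rbind(A = c(1, 1, 1), B = 1:3),
                                          c(0, 10, 20))), "A")
  # min-max mode maps to [0, 1]
  mm <- exprValues(normalizeSeries(es, "minmax"))
  expect_equal(range(mm["A", ]), c(0, 1))
})

test_that("three-level discretisation follows the symmetric and literal rules", {
  set.seed(2)
  g <- rnorm(54)
  mu <- mean(g); s <- sd(g)
  es <- makeSeries(rbind(A = g, B = rnorm(54)), seq_along(g) * 10 - 10)
  sym <- unname(states(discretizeSeries(es, "symmetric"))["A", ])
  lit <- unname(states(discretizeSeries(es, "literal"))["A", ])
  expect_identical(sym[g > mu + s], rep(3L, sum(g > mu + s)))
  expect_identical(sym[g < mu - s], rep(1L, sum(g < mu - s)))
  expect_identical(sym[g >= mu - s & g <= mu + s],
                   rep(2L, sum(g >= mu - s & g <= mu + s)))
  # literal: state 2 only on exact equality, so two states on continuous data
  expect_identical(lit[g > mu + s], rep(3L, sum(g > mu + s)))
  expect_identical(lit[g <= mu + s], rep(1L, sum(g <= mu + s)))
})

test_that("discretisation is invariant under per-gene affine rescaling", {
  set.seed(3)
  v <- matrix(rnorm(4 * 20), 4, 20)
  es <- makeSeries(v, seq_len(20))
  es2 <- makeSeries(v * 7 - 3, seq_len(20))
  expect_identical(states(discretizeSeries(es)), states(discretizeSeries(es2)))
  expect_identical(states(discretizeSeries(es, "literal")),
                   states(discretizeSeries(es2, "literal")))
})

test_that("filter -> impute -> normalise -> discretise always lands in {1,2,3}", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(3:6, 1); p <- sample(8:20, 1)
    v <- matrix(rnorm(n * p), n, p)
    v[runif(n * p) < 0.1] <- NA
    # guarantee feasibility: at least 4 observed per gene
    bad <- rowSums(!is.na(v)) < 4
    v[bad, 1:4] <- rnorm(sum(bad) * 4)
    es <- makeSeries(v, seq_len(p) * 5)
    ds <- discretizeSeries(normalizeSeries(imputeMissing(
      filterByMissingRate(es, 0.9))))
    expect_true(all(states(ds) %in% 1:3))
  }
})
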