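table5 <- builtin_fixture("topsis_table5")

test_that("vector normalization yields unit-norm, scale-invariant columns", {
  m <- decision_matrix(cbind(a = c(3, 4), b = c(2, 2)))
  y <- normalize_matrix(m)
  expect_equal(y[, "a"], c(0.6, 0.8), ignore_attr = TRUE)
  expect_equal(y[, "b"], rep(1 / sqrt(2), 2), ignore_attr = TRUE)
  # rescaling any column leaves the normalized matrix unchanged
  set.seed(1)
  X <- matrix(runif(30, 1, 10), 6, 5)
  y1 <- normalize_matrix(decision_matrix(X))
  X[, 3] <- X[, 3] * 737
  y2 <- normalize_matrix(decision_matrix(X))
  expect_equal(y1, y2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(y2^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("proportion columns sum to one", {
  p <- proportion_matrix(cbind(c(0.6, 0.8)))
  expect_equal(p[, 1], c(3 / 7, 4 / 7))
  set.seed(2)
  p2 <- proportion_matrix(normalize_matrix(matrix(runif(40, 1, 5), 8, 5)))
  expect_equal(colSums(p2), rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(proportion_matrix(cbind(rep(0.5, 4)))[, 1], rep(0.25, 4))
})

test_that("entropy is 1 for uniform columns and matches the formula", {
  expect_equal(entropy_values(cbind(c(0.5, 0.5))), 1)
  h <- entropy_values(cbind(c(3 / 7, 4 / 7)))
  expect_equal(h, -((3 / 7) * log(3 / 7) + (4 / 7) * log(4 / 7)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(h, 4), 0.9852)
  expect_error(entropy_values(cbind(1), a = 1), "at least 2")
  hh <- entropy_values(proportion_matrix(normalize_matrix(
    builtin_fixture("quality_table4")$indicators)))
  expect_true(all(hh >= 0 & hh <= 1))
})

test_that("entropy weights normalize to one and reject constant tables", {
  w <- entropy_weights(c(1, 0.5))
  expect_equal(w$weights, c(0, 1))
  expect_equal(entropy_weights(c(0.7, 0.7))$weights, c(0.5, 0.5))
  expect_error(entropy_weights(c(1, 1)), "degenerate")
  set.seed(3)
  for (i in 1:10) {
    X <- matrix(runif(6 * 4, 1, 9), 6, 4)
    w <- entropy_weights(entropy_values(proportion_matrix(
      normalize_matrix(X))))$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("weighting, ideals, separations and closeness behave at the edges", {
  n <- normalize_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  z <- weighted_matrix(n, c(0, 1))
  expect_equal(z[, 1], c(0, 0), ignore_attr = TRUE)
  expect_error(weighted_matrix(n, c(1, 2, 3)), "shape")

  one_row_ideals <- ideal_solutions(matrix(c(0.3, 0.7), 1))
  expect_equal(one_row_ideals$positive, one_row_ideals$negative)
  z2 <- rbind(c(2, 3), c(1, 1))
  ids <- ideal_solutions(z2)
  expect_equal(ids$positive, c(2, 3))
  expect_equal(ids$negative, c(1, 1))
  sep <- separation_distances(z2, ids)
  expect_equal(sep$d_plus[1], 0)
  expect_equal(sep$d_minus[2], 0)

  expect_equal(closeness(0, 0.4), 1)
  expect_equal(closeness(0.4, 0), 0)
  expect_equal(round(closeness(0.214, 0.119), 3), 0.357)
  expect_error(closeness(c(0, 0), c(0.1, 0)), "degenerate")
})

test_that("full run reproduces the published scoring table", {
  res <- run_topsis(builtin_fixture("quality_table4"))
  got <- as.data.frame(res)
  got <- got[match(table5$treatment, got$object), ]
  expect_true(all(abs(got$ci - table5$ci) <= 0.01))
  expect_identical(got$rank, as.integer(table5$rank))
  # separations on the reported scale track the published columns closely
  expect_true(all(abs(got$d_plus - table5$d_plus) <= 0.01))
  expect_true(all(abs(got$d_minus - table5$d_minus) <= 0.01))
  expect_false(res$ties)
  js <- jsonlite::fromJSON(topsis_result_json(res))
  expect_equal(js$ci, unname(res$closeness))
})

test_that("closeness is invariant to the separation-scale convention", {
  m <- builtin_fixture("quality_table4")$indicators
  r1 <- run_topsis(m, separation_scale = "rms")
  r2 <- run_topsis(m, separation_scale = "unit")
  expect_equal(r1$closeness, r2$closeness, tolerance = 1e-12)
  expect_equal(r1$d_plus, sqrt(nrow(m)) * r2$d_plus, tolerance = 1e-12)
})

test_that("a dominant object scores 1 and row order only permutes results", {
  m <- rbind(best = c(5, 6, 7), worst = c(1, 2, 3))
  res <- run_topsis(m)
  expect_equal(unname(res$closeness), c(1, 0))
  X <- builtin_fixture("quality_table4")$indicators
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  r1 <- run_topsis(X)
  r2 <- run_topsis(X[perm, ])
  expect_equal(r2$closeness, r1$closeness[perm], tolerance = 1e-12)
})

test_that("raising an entry of the weighted matrix never hurts that object", {
  closeness_from_weighted <- function(z) {
    ids <- ideal_solutions(z)
    sep <- separation_distances(z, ids)
    closeness(sep$d_plus, sep$d_minus)
  }
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(runif(8 * 5, 1, 9), 8, 5)
    y <- normalize_matrix(X)
    w <- entropy_weights(entropy_values(proportion_matrix(y)))
    z <- weighted_matrix(y, w)
    base <- closeness_from_weighted(z)
    i <- sample(8, 1); j <- sample(5, 1)
    z2 <- z
    z2[i, j] <- z2[i, j] * 1.25
    expect_gte(closeness_from_weighted(z2)[i], base[i] - 1e-12)
  }
})

test_that("pipeline closeness matches the naive formula oracle", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sample(3:12, 1); b <- sample(2:10, 1)
    X <- matrix(runif(a * b, 0.5, 20), a, b)
    res <- run_topsis(X)
    ora <- naive_topsis(X)
    expect_equal(unname(res$closeness), ora$ci, tolerance = 1e-10)
    expect_equal(unname(res$weights$weights), ora$weights, tolerance = 1e-10)
  }
})

test_that("goodness of fit equals Pearson correlation", {
  expect_equal(goodness_of_fit(1:5, 1:5), 1)
  expect_equal(goodness_of_fit(1:5, 5:1), -1)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)),
               stats::cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(round(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820)
  set.seed(5)
  x <- rnorm(30); y <- 0.3 * x + rnorm(30)
  expect_equal(goodness_of_fit(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_error(goodness_of_fit(c(1, 1, 1), 1:3), "constant")
})

test_that("degenerate decision matrices are rejected", {
  expect_error(decision_matrix(matrix(1, 1, 3)), "at least 2 objects")
  expect_error(decision_matrix(rbind(c(1, -2), c(3, 4))), "positive")
  expect_error(decision_matrix(rbind(c(1, NA), c(3, 4))), "missing")
  expect_error(run_topsis(matrix(1, 4, 3)), "degenerate")
})
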