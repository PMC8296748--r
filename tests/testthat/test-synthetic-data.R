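test_that("labels agree with a brute-force recomputation of W0", {
  d <- synthetic_graphs(n_graphs = 8, n_nodes = 5, n_selected = 2, seed = 42)
  sel <- attr(d, "selected_nodes")
  expect_length(sel, 2)
  w0 <- numeric(length(d))
  for (g in seq_along(d)) {
    W <- d[[g]]$features
    w1 <- 0; w2 <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      if (i %in% sel && j %in% sel) w1 <- w1 + W[i, j]
      if (xor(i %in% sel, j %in% sel)) w2 <- w2 + W[i, j]
    }
    w0[g] <- 2 * w1 + w2
  }
  expect_equal(w0, attr(d, "w0"), tolerance = 1e-12)
  expect_equal(mean(w0), attr(d, "w0_mean"), tolerance = 1e-12)
  expect_identical(dataset_labels(d), as.integer(w0 > mean(w0)))
})

test_that("synthetic graphs are complete, symmetric and unit-diagonal", {
  d <- synthetic_graphs(n_graphs = 5, n_nodes = 10, n_selected = 4, seed = 7)
  for (g in d) {
    expect_equal(g$adj, t(g$adj))
    expect_equal(diag(g$features), rep(1, 10))
    expect_identical(edge_count(g), 100L)
    expect_true(all(g$adj >= 0 & g$adj <= 1))
    expect_identical(g$features, g$adj)
  }
})

test_that("generation is bit-identical under a fixed seed and balanced", {
  d1 <- synthetic_graphs(n_graphs = 400, n_nodes = 12, n_selected = 6, seed = 9)
  d2 <- synthetic_graphs(n_graphs = 400, n_nodes = 12, n_selected = 6, seed = 9)
  expect_identical(d1[[137]]$features, d2[[137]]$features)
  expect_identical(dataset_labels(d1), dataset_labels(d2))
  expect_identical(attr(d1, "selected_nodes"), attr(d2, "selected_nodes"))

  # labels split about evenly (binomial noise around 1/2)
  frac <- mean(dataset_labels(d1))
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(400) + 0.05)

  # edge weights average 1/2 within 3 standard errors
  w <- unlist(lapply(d1[1:50], function(g) flatten_upper_triangle(g$features)))
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 0.5), 3 * se + 1e-3)
})

test_that("degenerate generator specs are rejected", {
  expect_error(synthetic_graphs(10, 10, 10, seed = 1), "n_selected")
  expect_error(synthetic_graphs(10, 10, 0, seed = 1), "n_selected")
  expect_error(synthetic_graphs(1, 10, 5, seed = 1), "2 graphs")
  expect_error(synthetic_graphs(10, 10, 5, seed = 1, weight_range = c(1, 1)),
               "weight_range")
})

test_that("split_folds produces disjoint, exhaustive, balanced partitions", {
  f <- split_folds(1035, k = 5, seed = 1)
  expect_identical(lengths(f), rep(207L, 5))
  expect_identical(sort(unlist(f)), 1:1035)

  f7 <- split_folds(7, k = 5, seed = 2)
  expect_lte(diff(range(lengths(f7))), 1)
  expect_identical(sort(unlist(f7)), 1:7)

  expect_identical(split_folds(50, 5, seed = 3), split_folds(50, 5, seed = 3))
  expect_error(split_folds(4, 5, seed = 1), "folds")
})

test_that("a linear margin classifier separates the synthetic classes", {
  # the label is a linear functional of the flattened weights thresholded
  # at its mean, so any linear model should beat chance by a wide margin
  d <- synthetic_graphs(n_graphs = 600, n_nodes = 15, n_selected = 7, seed = 21)
  X <- dataset_features(d)
  y <- dataset_labels(d)
  tr <- 1:450; te <- 451:600
  sc <- gatnet:::fit_linear_svm(X[tr, ], y[tr])(X[te, ])
  expect_gt(mean((sc > 0) == (y[te] == 1)), 0.75)
})
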