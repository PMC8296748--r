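test_that("pearson_connectivity reproduces textbook correlations", {
  set.seed(1)
  x <- rnorm(20)
  ts <- cbind(a = x, b = x, c = -x, d = rnorm(20))
  cm <- pearson_connectivity(ts)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_equal(dim(cm), c(4, 4))
  expect_equal(unclass(cm), t(unclass(cm)))

  # fixed 3-region, 4-timepoint table against the explicit formula
  ts3 <- cbind(r1 = c(1, 2, 4, 3), r2 = c(2, 1, 5, 4), r3 = c(10, 8, 7, 2))
  cm3 <- pearson_connectivity(ts3)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm3[i, j], oracle_pearson_pair(ts3[, i], ts3[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(unclass(cm3)), rep(1, 3), ignore_attr = TRUE)
})

test_that("pearson_connectivity is invariant to positive affine rescaling", {
  set.seed(2)
  ts <- matrix(rnorm(60), 15, 4)
  scaled <- sweep(sweep(ts, 2, c(2, 0.5, 10, 1), `*`), 2, c(-3, 0, 7, 100), `+`)
  expect_equal(unclass(pearson_connectivity(ts)),
               unclass(pearson_connectivity(scaled)), tolerance = 1e-12)
})

test_that("degenerate time series are handled as specified", {
  ts <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(4, 2, 6, 1))
  expect_warning(cm <- pearson_connectivity(ts), "constant")
  expect_equal(cm["a", "b"], 0)
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["b", "c"], cor(ts[, 2], ts[, 3]))
  expect_error(pearson_connectivity(ts[1:2, ]), "timepoints")
  expect_error(pearson_connectivity(cbind(ts, d = c(NA, 1, 2, 3))), "missing")
})

test_that("build_graph thresholds structure but never the feature rows", {
  m <- matrix(c(1, 0.5, -0.2,
                0.5, 1, 0.2,
                -0.2, 0.2, 1), 3, 3)
  cm <- as_connectivity_matrix(m)
  g <- build_graph(cm, label = 1, threshold = 0.3)
  # enumerated: 3 self-loops + the symmetric 0.5 pair survive
  expect_equal(edge_count(g), 5L)
  expect_equal(g$adj[1, 3], 0)
  expect_equal(g$adj[2, 3], 0)
  expect_equal(g$adj[1, 2], 0.5)
  expect_equal(g$features, unclass(cm))  # signed rows untouched

  # strict inequality at the boundary
  g_eq <- build_graph(cm, label = 0, threshold = 0.5)
  expect_equal(edge_count(g_eq), 3L)  # only self-loops survive
  expect_error(build_graph(cm, label = 0, threshold = 1), "threshold")
  expect_error(build_graph(cm, label = 0, threshold = -0.1), "threshold")
})

test_that("dense 110-node graphs have 12100 edges and flatten to 5995", {
  m <- random_connectivity(110, seed = 3)
  g <- build_graph(as_connectivity_matrix(m), label = 0, threshold = NULL)
  expect_identical(edge_count(g), 12100L)
  expect_equal(graph_sparsity(g), 0)
  expect_length(flatten_upper_triangle(m), 5995L)
})

test_that("edge count is monotonically non-increasing in the threshold", {
  m <- random_connectivity(20, seed = 4)
  cm <- as_connectivity_matrix(m)
  counts <- sapply(seq(0, 0.95, by = 0.05), function(t)
    edge_count(build_graph(cm, 0, threshold = t)))
  expect_true(all(diff(counts) <= 0))
  # threshold just below 1 keeps only the diagonal
  expect_equal(counts[length(counts)] >= 20, TRUE)
  g_hi <- build_graph(cm, 0, threshold = 1 - 1e-12)
  expect_identical(edge_count(g_hi), 20L)
})

test_that("flatten_upper_triangle uses row-major order and N(N-1)/2 length", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- 0  # fill explicitly below
  m <- rbind(c(1, 2, 3), c(2, 1, 4), c(3, 4, 1))
  expect_equal(flatten_upper_triangle(m), c(2, 3, 4))
  for (n in 2:12) {
    expect_length(flatten_upper_triangle(random_connectivity(n, seed = n)),
                  n * (n - 1) / 2)
  }
  expect_error(flatten_upper_triangle(matrix(1, 1, 1)), "N >= 2")
})

test_that("sparsity matches the retained-edge bookkeeping", {
  # graph with exactly 10056 of the 12100 dense entries retained
  n <- 110
  adj <- diag(n)
  off <- which(upper.tri(adj), arr.ind = TRUE)
  keep <- off[seq_len((10056 - n) / 2), , drop = FALSE]
  adj[keep] <- 0.5
  adj[keep[, c(2, 1)]] <- 0.5
  g <- new_graph_sample(features = adj, adj = adj, label = 0)
  expect_identical(edge_count(g), 10056L)
  expect_equal(graph_sparsity(g), (12100 - 10056) / 12100, tolerance = 1e-12)
  expect_equal(round(graph_sparsity(g), 4), 0.1689)

  g0 <- new_graph_sample(features = adj, adj = matrix(0, n, n), label = 0)
  expect_equal(graph_sparsity(g0), 1)
})

test_that("neighbor sets include self-loops that survive thresholding", {
  m <- random_connectivity(6, seed = 5)
  g <- build_graph(as_connectivity_matrix(m), 0, threshold = 0.8)
  ns <- neighbor_sets(g)
  for (i in seq_len(6)) expect_true(i %in% ns[[i]])
})
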