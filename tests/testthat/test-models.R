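make_complete_neigh <- function(n) lapply(seq_len(n), function(i) seq_len(n))

test_that("attention coefficients normalize over each neighborhood", {
  set.seed(20)
  h <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 2, 3)
  a <- rnorm(4)
  neigh <- list(c(1L, 2L), c(1L, 2L, 3L), 3L, c(2L, 4L))
  A <- attention_coefficients(h, W, a, neigh)
  expect_equal(rowSums(A), rep(1, 4))
  expect_true(all(A >= 0))
  expect_equal(A[3, 3], 1)                 # single neighbor -> coefficient 1
  expect_equal(A[1, 3:4], c(0, 0))         # masked outside the neighborhood

  # identical features give uniform coefficients
  hu <- matrix(1, 4, 3)
  Au <- attention_coefficients(hu, W, a, make_complete_neigh(4))
  expect_equal(Au, matrix(0.25, 4, 4))

  expect_error(attention_coefficients(h, W, a, list(1:2, 2:3, integer(), 4L)),
               "empty neighborhood")
})

test_that("a 3-node scalar head matches a term-by-term transcript", {
  h <- matrix(c(0.5, -1, 2), 3, 1)
  W <- matrix(1.5, 1, 1)
  a <- c(0.7, -0.3)
  neigh <- make_complete_neigh(3)
  A <- attention_coefficients(h, W, a, neigh, slope = 0.2)
  z <- 1.5 * h[, 1]
  for (i in 1:3) {
    e <- sapply(1:3, function(j) {
      s <- 0.7 * z[i] - 0.3 * z[j]
      if (s > 0) s else 0.2 * s
    })
    expect_equal(A[i, ], exp(e - max(e)) / sum(exp(e - max(e))), tolerance = 1e-12)
  }
})

test_that("gat_layer matches the explicit-loop oracle and its edge cases", {
  set.seed(21)
  h <- matrix(rnorm(15), 5, 3)
  neigh <- make_complete_neigh(5)
  heads <- list(list(W = matrix(rnorm(6), 2, 3), a = rnorm(4)),
                list(W = matrix(rnorm(6), 2, 3), a = rnorm(4)))
  out <- gat_layer(h, heads, neigh, combine = "concat", activation = "leaky_relu")
  expect_equal(dim(out), c(5, 4))
  for (k in 1:2) {
    o <- oracle_attention_head(h, heads[[k]]$W, heads[[k]]$a, neigh)
    expect_equal(out[, (2 * k - 1):(2 * k)], o_lrelu(o$U), tolerance = 1e-10)
  }
  # single head: concat and average agree
  out1c <- gat_layer(h, heads[1], neigh, "concat", "sigmoid")
  out1a <- gat_layer(h, heads[1], neigh, "average", "sigmoid")
  expect_equal(out1c, out1a)
  # zero weights: activation of zero everywhere
  hz <- list(list(W = matrix(0, 2, 3), a = rnorm(4)))
  expect_equal(gat_layer(h, hz, neigh, "average", "sigmoid"),
               matrix(0.5, 5, 2))
})

test_that("attention pooling and weighted prediction behave per definition", {
  set.seed(22)
  h <- matrix(rnorm(12), 4, 3)
  expect_equal(attention_pool(h, c(0, 0, 0)), rep(0.5, 4))
  expect_equal(attention_pool(h, c(1e3, 0, 0)), as.numeric(h[, 1] > 0),
               tolerance = 1e-6)
  wp <- rnorm(3)
  expect_equal(attention_pool(h, wp), o_sigma(drop(h %*% wp)), tolerance = 1e-12)

  P <- c(0.2, 0.7, 0.4)
  WA <- matrix(rnorm(9), 3, 3)
  pr <- attention_predict(P, WA)
  expect_equal(sum(pr$weights), 1)
  expect_true(all(pr$weights >= 0))
  expect_gte(pr$prob, min(P) - 1e-12); expect_lte(pr$prob, max(P) + 1e-12)
  # hand-rolled softmax + dot product
  s <- drop(WA %*% P)
  expect_equal(pr$prob, sum(o_softmax(s) * P), tolerance = 1e-12)
  # zero prediction weights reduce to the average head
  expect_equal(attention_predict(P, matrix(0, 3, 3))$prob, gat_average_predict(P))
  # constant node scores are preserved by any convex combination
  expect_equal(attention_predict(rep(0.37, 3), WA)$prob, 0.37)
  expect_error(attention_predict(P, matrix(0, 2, 2)), "N x N")
})

test_that("dense head and learnable pooling blocks satisfy their contracts", {
  set.seed(23)
  h <- matrix(rnorm(8), 4, 2)
  fc0 <- list(W1 = matrix(0, 3, 8), b1 = rep(0, 3), W2 = matrix(0, 2, 3), b2 = c(0, 0))
  expect_equal(gat_fc_predict(h, fc0), c(0.5, 0.5))
  fc <- list(W1 = matrix(rnorm(24), 3, 8), b1 = rnorm(3),
             W2 = matrix(rnorm(6), 2, 3), b2 = rnorm(2))
  p <- gat_fc_predict(h, fc)
  expect_equal(sum(p), 1)
  # flattening is row-major (node vectors spliced)
  x <- as.numeric(t(h))
  z1 <- o_lrelu(drop(fc$W1 %*% x) + fc$b1)
  expect_equal(p, o_softmax(drop(fc$W2 %*% z1) + fc$b2), tolerance = 1e-12)

  Y <- matrix(rnorm(44), 4, 11)
  expect_equal(drop(learn_pool(Y, rep(1 / 4, 4))), colMeans(Y))
  expect_equal(drop(learn_pool(Y, c(0, 0, 1, 0))), Y[3, ])
  S <- matrix(rnorm(4), 4, 1)
  man <- sapply(1:11, function(j) sum(S[, 1] * Y[, j]))
  expect_equal(drop(learn_pool(Y, S)), man, tolerance = 1e-12)
  expect_equal(dim(learn_pool(Y, S)), c(1, 11))
  expect_error(learn_pool(Y, matrix(1, 3, 1)), "N x 1")
})

test_that("gcn_layer reduces correctly on identity graphs and matches loops", {
  set.seed(24)
  h <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(6), 2, 3)
  # identity adjacency: normalized propagation is the identity
  expect_equal(gcn_layer(h, diag(3), W), o_lrelu(h %*% t(W)), tolerance = 1e-12)

  adj <- matrix(c(1, .5, 0, .5, 1, .3, 0, .3, 1), 3, 3)
  d <- rowSums(adj)
  M <- adj / sqrt(outer(d, d))
  expect_equal(gcn_layer(h, adj, W), o_lrelu(M %*% h %*% t(W)), tolerance = 1e-12)

  # chebyshev order 1 is an affine function of the scaled Laplacian
  Ws <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3))
  got <- gcn_layer(h, adj, Ws, filter = "chebyshev", order = 1)
  Lt <- -M
  expect_equal(got, o_lrelu(h %*% t(Ws[[1]]) + Lt %*% h %*% t(Ws[[2]])),
               tolerance = 1e-12)
})

test_that("compiled forward equals the block composition and loop oracle", {
  set.seed(25)
  d <- synthetic_graphs(n_graphs = 4, n_nodes = 5, n_selected = 2, seed = 31)
  cfg <- gat_config(5, 5, "gat2", heads = c(2, 2), units = c(3, 3))
  net <- gat_network(cfg, seed = 8)
  cf <- coef(net)
  probs <- predict(net, d)
  for (b in seq_along(d)) {
    o <- oracle_gat2_forward(d[[b]]$features, d[[b]]$adj, cf,
                             heads = c(2, 2), units = c(3, 3))
    expect_equal(probs[b], o$prob, tolerance = 1e-10)
    # block composition route
    neigh <- neighbor_sets(d[[b]])
    h1 <- gat_layer(d[[b]]$features,
                    list(list(W = cf$W_l1_h1, a = cf$a_l1_h1),
                         list(W = cf$W_l1_h2, a = cf$a_l1_h2)),
                    neigh, "concat", "sigmoid")
    h2 <- gat_layer(h1,
                    list(list(W = cf$W_l2_h1, a = cf$a_l2_h1),
                         list(W = cf$W_l2_h2, a = cf$a_l2_h2)),
                    neigh, "average", "sigmoid")
    P <- attention_pool(h2, cf$wp)
    expect_equal(attention_predict(P, cf$WA)$prob, probs[b], tolerance = 1e-10)
  }
})

test_that("forward invariants hold across random graphs and parameters", {
  for (seed in 1:5) {
    d <- synthetic_graphs(n_graphs = 2, n_nodes = 6, n_selected = 3, seed = seed)
    cfg <- gat_config(6, 6, "gat2", heads = c(3, 2), units = c(4, 3))
    net <- gat_network(cfg, seed = seed + 100)
    det <- predict(net, d, type = "detail")
    for (dd in det) {
      expect_true(dd$prob > 0 && dd$prob < 1)
      expect_equal(sum(dd$contribution_weights), 1, tolerance = 1e-12)
      expect_true(all(dd$contribution_weights >= 0))
      for (layer in dd$attention) for (A in layer) {
        expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
        expect_true(all(A >= -1e-15))
      }
      expect_true(all(dd$node_scores > 0 & dd$node_scores < 1))
    }
  }
})

test_that("zeroed prediction weights reproduce the average head bitwise", {
  d <- synthetic_graphs(n_graphs = 6, n_nodes = 7, n_selected = 3, seed = 41)
  cfg2 <- gat_config(7, 7, "gat2", heads = c(2, 2), units = c(3, 3))
  cfga <- gat_config(7, 7, "gat_average", heads = c(2, 2), units = c(3, 3))
  net2 <- gat_network(cfg2, seed = 5)
  neta <- gat_network(cfga, seed = 5)
  # share every upstream tensor, zero the prediction weights
  cf <- coef(net2)
  cf$WA <- matrix(0, 7, 7)
  net2 <- set_coef(net2, cf)
  shared <- coef(net2)[names(coef(neta))]
  neta <- set_coef(neta, shared)
  expect_identical(predict(net2, d), predict(neta, d))
})

test_that("node relabeling leaves the average-head prediction unchanged", {
  d <- synthetic_graphs(n_graphs = 2, n_nodes = 6, n_selected = 3, seed = 51)
  g <- d[[1]]
  cfg <- gat_config(6, 6, "gat_average", heads = c(2, 2), units = c(3, 3))
  net <- gat_network(cfg, seed = 9)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  gp <- new_graph_sample(features = g$features[perm, perm],
                         adj = g$adj[perm, perm], label = g$label)
  # permute the feature dimension of the first-layer weights accordingly
  cf <- coef(net)
  cfp <- cf
  for (k in 1:2) cfp[[sprintf("W_l1_h%d", k)]] <- cf[[sprintf("W_l1_h%d", k)]][, perm]
  netp <- set_coef(net, cfp)
  p0 <- predict(net, as_graph_dataset(list(g)))
  pp <- predict(netp, as_graph_dataset(list(gp)))
  expect_equal(pp, p0, tolerance = 1e-12)
})

test_that("backward pass matches central finite differences", {
  d <- synthetic_graphs(n_graphs = 2, n_nodes = 4, n_selected = 2, seed = 61)
  da <- gatnet:::dataset_arrays(d)
  eps <- 1e-6
  for (m in c("gat2", "gat_fc", "gcn_at_cheby")) {
    cfg <- gat_config(4, 4, m, heads = c(2, 2), units = c(3, 3))
    net <- gat_network(cfg, seed = 13)
    ccfg <- gatnet:::cfg_for_cpp(cfg)
    th <- net$theta
    res <- gatnet:::cpp_batch(da$X, da$A, da$y, ccfg, th, grad = TRUE)
    f <- function(t) gatnet:::cpp_batch(da$X, da$A, da$y, ccfg, t)$loss
    num <- vapply(seq_along(th), function(i) {
      tp <- th; tp[i] <- tp[i] + eps
      tm <- th; tm[i] <- tm[i] - eps
      (f(tp) - f(tm)) / (2 * eps)
    }, 0.0)
    expect_lt(max(abs(num - res$grad) / pmax(abs(num), 1e-3)), 1e-4)
  }
})
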