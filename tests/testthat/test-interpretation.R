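test_that("the all-ones mask reproduces unmasked predictions exactly", {
  tt <- trained_toy()
  d <- tt$data[261:300]
  masked <- lapply(d, function(g) { g$features <- g$features * 1; g })
  attributes(masked) <- attributes(d)
  expect_identical(predict(tt$fit, masked), predict(tt$fit, d))
})

test_that("mask optimization keeps entries in [0,1] and does not increase loss", {
  tt <- trained_toy()
  mk <- learn_feature_mask(tt$fit, tt$data[241:270], steps = 25,
                           l1 = 0, entropy = 0, init_noise = 0, seed = 1)
  expect_true(all(mk >= 0 & mk <= 1))
  h <- attr(mk, "history")
  expect_lte(h[length(h)], h[1] + 1e-8)
  # with penalties the entries still stay in range
  mk2 <- learn_feature_mask(tt$fit, tt$data[241:270], steps = 10, seed = 1)
  expect_true(all(mk2 >= 0 & mk2 <= 1))
})

test_that("saliency matches central finite differences on a toy model", {
  d <- synthetic_graphs(n_graphs = 3, n_nodes = 4, n_selected = 2, seed = 91)
  cfg <- gat_config(4, 4, "gat2", heads = c(2, 2), units = c(3, 3))
  net <- gat_network(cfg, seed = 17)
  rk <- saliency(net, d)
  sc <- attr(rk, "scores")
  da <- gatnet:::dataset_arrays(d)
  ccfg <- gatnet:::cfg_for_cpp(cfg)
  eps <- 1e-5
  # average the per-sample loss gradient across samples, then |.|
  num <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    g <- numeric(3)
    for (b in 1:3) {
      Xp <- da$X; Xp[i, j, b] <- Xp[i, j, b] + eps
      Xm <- da$X; Xm[i, j, b] <- Xm[i, j, b] - eps
      g[b] <- (gatnet:::cpp_batch(Xp, da$A, da$y, ccfg, net$theta)$loss -
               gatnet:::cpp_batch(Xm, da$A, da$y, ccfg, net$theta)$loss) / (2 * eps)
    }
    num[i, j] <- abs(mean(g))
  }
  expect_lt(max(abs(sc - num) / pmax(num, 1e-3)), 1e-4)
})

test_that("saliency of a model with a zeroed head is identically zero", {
  cfg <- gat_config(5, 5, "gat2", heads = c(2, 2), units = c(3, 3))
  net <- gat_network(cfg, seed = 19)
  net <- set_coef(net, list(wp = rep(0, 3), WA = matrix(0, 5, 5)))
  d <- synthetic_graphs(n_graphs = 4, n_nodes = 5, n_selected = 2, seed = 92)
  rk <- saliency(net, d)
  expect_equal(max(attr(rk, "scores")), 0)
})

test_that("rank_features orders by score with deterministic tie-breaking", {
  sc <- matrix(c(0.5, 0.9, 0.5, 0.1), 2, 2)
  rk <- rank_features(sc)
  expect_equal(rk$score, c(0.9, 0.5, 0.5, 0.1))
  # tie between (1,1) and (1,2): node index first, then feature index
  expect_equal(rk$node[2:3], c(1, 1))
  expect_equal(rk$feature[2:3], c(1, 2))
})

test_that("hack_features zeroes exactly the ranked entries and is pure", {
  d <- synthetic_graphs(n_graphs = 3, n_nodes = 6, n_selected = 3, seed = 93)
  sc <- matrix(runif(36), 6, 6)
  rk <- rank_features(sc)
  before <- d[[2]]$features
  h0 <- hack_features(d, rk, 0)
  expect_identical(h0[[2]]$features, before)
  h3 <- hack_features(d, rk, 3)
  expect_identical(d[[2]]$features, before)  # input untouched
  pos <- cbind(rk$node[1:3], rk$feature[1:3])
  for (g in h3) expect_equal(g$features[pos], rep(0, 3))
  changed <- h3[[2]]$features != before
  expect_identical(sum(changed), 3L)
  # idempotent and exhaustive
  expect_identical(hack_features(h3, rk, 3)[[2]]$features, h3[[2]]$features)
  hall <- hack_features(d, rk, 36)
  expect_equal(max(abs(hall[[1]]$features)), 0)
  expect_identical(hall[[1]]$adj, d[[1]]$adj)  # structure untouched
  expect_error(hack_features(d, rk, -1), "non-negative")
  expect_error(hack_features(d, rk, 37), "exceeds")
})

test_that("k = 0 perturbation reports zero CPP and NLCI, metrics unchanged", {
  tt <- trained_toy()
  d <- tt$data[281:300]
  rk <- saliency(tt$fit, d)
  rep0 <- perturb_evaluate(tt$fit, d, rk, ks = c(0, 20))
  expect_equal(rep0$cpp[1], 0)
  expect_equal(rep0$nlci[1], 0)
  base <- classification_metrics(dataset_labels(d), predict(tt$fit, d))
  expect_equal(rep0$accuracy[1], base[["accuracy"]])
  # cpp is the mean absolute probability change by definition
  p0 <- predict(tt$fit, d)
  p20 <- predict(tt$fit, hack_features(d, rk, 20))
  expect_equal(rep0$cpp[2], mean(abs(p20 - p0)), tolerance = 1e-12)
  expect_equal(rep0$nlci[2], sum((p20 > 0.5) != (p0 > 0.5)))
})

test_that("hacking the mask's top features changes the model's predictions", {
  # single-seed sanity check; the multi-seed deletion-fidelity
  # comparison runs with the acceptance suite
  tt <- trained_toy()
  test <- tt$data[241:300]
  mk <- learn_feature_mask(tt$fit, test, steps = 60, seed = 1)
  rk <- rank_features(mk)
  p0 <- predict(tt$fit, test)
  p1 <- predict(tt$fit, hack_features(test, rk, 24))
  expect_gt(mean(abs(p1 - p0)), 0)
  # deeper cuts move predictions at least as much on average
  p2 <- predict(tt$fit, hack_features(test, rk, 72))
  expect_gte(mean(abs(p2 - p0)) + 0.02, mean(abs(p1 - p0)))
})

test_that("perturbation effect grows with k on average", {
  tt <- trained_toy()
  d <- tt$data[241:300]
  mk <- learn_feature_mask(tt$fit, d, steps = 40, seed = 2)
  rk <- rank_features(mk)
  rep <- perturb_evaluate(tt$fit, d, rk, ks = c(0, 12, 48, 144))
  expect_true(all(diff(rep$cpp) >= -0.02))   # non-decreasing trend
  expect_gte(rep$cpp[4], rep$cpp[1])
  expect_gte(rep$nlci[4], rep$nlci[1])
})

test_that("top_connections reports group means and Welch t-tests", {
  # identical groups: zero difference, p = 1
  g <- synthetic_graphs(n_graphs = 4, n_nodes = 6, n_selected = 3, seed = 94)
  pair <- lapply(1:4, function(i) {
    s <- g[[i]]
    s$label <- as.integer(i <= 2)
    s
  })
  pair[[3]]$features <- pair[[1]]$features; pair[[3]]$adj <- pair[[1]]$adj
  pair[[4]]$features <- pair[[2]]$features; pair[[4]]$adj <- pair[[2]]$adj
  dd <- as_graph_dataset(pair)
  sc <- matrix(runif(36), 6, 6)
  tc <- top_connections(dd, sc, top_n = 5)
  expect_equal(tc$difference, rep(0, 5))
  expect_equal(tc$p_value, rep(1, 5))

  # zero-variance unequal constants: documented degenerate branch
  con <- lapply(1:4, function(i) {
    f <- matrix(if (i <= 2) 0.8 else 0.2, 6, 6); diag(f) <- 1
    new_graph_sample(f, abs(f), label = as.integer(i <= 2))
  })
  tcc <- top_connections(as_graph_dataset(con), sc, top_n = 3)
  expect_equal(tcc$difference, rep(0.6, 3), tolerance = 1e-12)
  expect_equal(tcc$p_value, rep(0, 3))

  # Welch statistic against the hand formula
  set.seed(95)
  d2 <- synthetic_graphs(n_graphs = 30, n_nodes = 6, n_selected = 3, seed = 96)
  tc2 <- top_connections(d2, sc, top_n = 4)
  y <- dataset_labels(d2)
  for (r in 1:4) {
    v1 <- sapply(d2[y == 1], function(s) s$features[tc2$node_i[r], tc2$node_j[r]])
    v0 <- sapply(d2[y == 0], function(s) s$features[tc2$node_i[r], tc2$node_j[r]])
    tstat <- (mean(v1) - mean(v0)) / sqrt(var(v1) / length(v1) + var(v0) / length(v0))
    df <- (var(v1) / length(v1) + var(v0) / length(v0))^2 /
      ((var(v1) / length(v1))^2 / (length(v1) - 1) +
       (var(v0) / length(v0))^2 / (length(v0) - 1))
    expect_equal(tc2$p_value[r], 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  }
  # symmetric duplicates are collapsed: every pair appears once
  expect_true(all(tc2$node_i < tc2$node_j))
})
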