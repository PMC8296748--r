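# Independent brute-force oracles used across the test files. These are
# deliberately written as explicit loops over the defining formulas, not
# as calls into the package's own computational path.

# textbook Pearson coefficient of two vectors
oracle_pearson_pair <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# leaky relu / sigmoid / softmax as scalar helpers
o_lrelu <- function(x, s = 0.2) ifelse(x > 0, x, s * x)
o_sigma <- function(x) 1 / (1 + exp(-x))
o_softmax <- function(x) exp(x - max(x)) / sum(exp(x - max(x)))

# one attention head evaluated node by node with explicit loops
oracle_attention_head <- function(H, W, a, neigh, slope = 0.2) {
  n <- nrow(H)
  fp <- nrow(W)
  Z <- matrix(0, n, fp)
  for (i in seq_len(n)) Z[i, ] <- W %*% H[i, ]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- sapply(neigh[[i]], function(j)
      o_lrelu(sum(a * c(Z[i, ], Z[j, ])), slope))
    A[i, neigh[[i]]] <- o_softmax(e)
  }
  U <- matrix(0, n, fp)
  for (i in seq_len(n)) for (j in neigh[[i]])
    U[i, ] <- U[i, ] + A[i, j] * Z[j, ]
  list(A = A, U = U, Z = Z)
}

# full attention-pooling classifier forward pass via loops, given the
# coef() list of a two-layer model with default activations (sigmoid
# head outputs on both layers, concatenated then averaged; sigmoid
# pooling; softmax-weighted prediction)
oracle_gat2_forward <- function(H, adjacency, cf, heads, units, slope = 0.2) {
  neigh <- apply(adjacency > 0, 1, which, simplify = FALSE)
  h1 <- NULL
  for (k in seq_len(heads[1])) {
    hd <- oracle_attention_head(H, cf[[sprintf("W_l1_h%d", k)]],
                                cf[[sprintf("a_l1_h%d", k)]], neigh, slope)
    h1 <- cbind(h1, o_sigma(hd$U))
  }
  Usum <- 0
  for (k in seq_len(heads[2])) {
    hd <- oracle_attention_head(h1, cf[[sprintf("W_l2_h%d", k)]],
                                cf[[sprintf("a_l2_h%d", k)]], neigh, slope)
    Usum <- Usum + hd$U
  }
  h2 <- o_sigma(Usum / heads[2])
  P <- o_sigma(drop(h2 %*% cf$wp))
  A <- o_softmax(drop(cf$WA %*% P))
  list(prob = sum(A * P), P = P, A = A)
}

# metric suite recomputed through a different route: reconstruct binary
# label/prediction vectors and use their elementary statistics
oracle_metrics <- function(TP, FP, TN, FN) {
  lab <- c(rep(1, TP), rep(1, FN), rep(0, TN), rep(0, FP))
  pred <- c(rep(1, TP), rep(0, FN), rep(0, TN), rep(1, FP))
  prec_den <- TP + FP
  rec_den <- TP + FN
  prec <- if (prec_den) TP / prec_den else NA_real_
  rec <- if (rec_den) TP / rec_den else NA_real_
  # harmonic mean of precision and recall, with the usual conventions:
  # undefined when there are no positives at all, zero whenever TP = 0
  f1 <- if (2 * TP + FP + FN == 0) NA_real_
        else if (TP == 0) 0
        else 2 * prec * rec / (prec + rec)
  mcc <- suppressWarnings(cor(pred, lab))
  if (is.na(mcc)) mcc <- 0
  list(accuracy = mean(pred == lab),
       sensitivity = rec,
       specificity = if (TN + FP) TN / (TN + FP) else NA_real_,
       f1 = f1, mcc = mcc)
}

# random symmetric correlation-like matrix with unit diagonal
random_connectivity <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# small trained model on a small synthetic dataset, shared by the
# interpretation tests (cached per session)
trained_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- synthetic_graphs(n_graphs = 300, n_nodes = 12, n_selected = 6, seed = 11)
      fit <- gat_fit(d[1:240], model = "gat2", heads = c(2, 2), units = c(8, 8),
                     validation = d[241:300],
                     control = gat_control(learning_rate = 1e-3, max_epochs = 60,
                                           seed = 4))
      cache <<- list(fit = fit, data = d)
    }
    cache
  }
})
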