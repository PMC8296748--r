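# Reference implementations of the individual network blocks, written to
# mirror the defining equations one term at a time. The fitting code runs
# a compiled implementation of the same math; tests assert the two agree.

#' Masked attention coefficients of one attention head
#'
#' For each node i the unnormalized score against neighbor j is
#' `LeakyReLU(a' [W h_i || W h_j])`; a softmax over the structural
#' neighborhood N_i (masked attention) yields coefficients that are
#' non-negative and sum to one per node.
#'
#' @param h N x F node feature matrix (rows are nodes).
#' @param W F' x F head weight matrix.
#' @param a attention vector of length 2F'.
#' @param neighbors list of neighbor index vectors (see [neighbor_sets()]);
#'   every set must be nonempty.
#' @param slope negative slope of the leaky ReLU (default 0.2).
#' @return N x N matrix of coefficients, zero outside each neighborhood,
#'   rows summing to 1.
#' @export
attention_coefficients <- function(h, W, a, neighbors, slope = 0.2) {
  h <- as.matrix(h); W <- as.matrix(W)
  fp <- nrow(W)
  stopifnot(length(a) == 2 * fp, ncol(W) == ncol(h))
  n <- nrow(h)
  stopifnot(length(neighbors) == n)
  if (any(lengths(neighbors) == 0))
    stopf("empty neighborhood: attention cannot be normalized")
  Z <- h %*% t(W)
  f <- drop(Z %*% a[seq_len(fp)])
  g <- drop(Z %*% a[fp + seq_len(fp)])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- neighbors[[i]]
    e <- leaky_relu(f[i] + g[js], slope)
    A[i, js] <- softmax_vec(e)
  }
  A
}

#' One multi-head graph attention layer
#'
#' Each head aggregates neighbor representations with its attention
#' coefficients; hidden layers concatenate the activated head outputs,
#' the final layer averages the raw head outputs before the activation.
#'
#' @param h N x F node feature matrix.
#' @param heads list of heads, each a list with elements `W` (F' x F) and
#'   `a` (length 2F').
#' @param neighbors neighbor index sets.
#' @param combine `"concat"` or `"average"`.
#' @param activation `"leaky_relu"`, `"sigmoid"` or `"identity"`.
#' @param slope leaky ReLU slope for both scores and activation.
#' @return N x (K F') matrix for concat, N x F' for average.
#' @export
gat_layer <- function(h, heads, neighbors, combine = c("concat", "average"),
                      activation = c("leaky_relu", "sigmoid", "identity"),
                      slope = 0.2) {
  combine <- match.arg(combine)
  activation <- match.arg(activation)
  h <- as.matrix(h)
  act <- switch(activation,
                leaky_relu = function(x) leaky_relu(x, slope),
                sigmoid = sigmoid, identity = identity)
  outs <- lapply(heads, function(hd) {
    A <- attention_coefficients(h, hd$W, hd$a, neighbors, slope)
    A %*% (h %*% t(as.matrix(hd$W)))
  })
  if (combine == "concat") {
    do.call(cbind, lapply(outs, act))
  } else {
    act(Reduce(`+`, outs) / length(outs))
  }
}

#' Attention pooling: per-node graph-representation scores
#'
#' Maps every node representation to a single score through one shared
#' weight vector and a sigmoid, `P_i = sigmoid(w_p . h'_i)`, giving a
#' graph representation whose dimension equals the number of nodes.
#'
#' @param h N x F' node representation matrix.
#' @param wp pooling weight vector of length F'.
#' @return Numeric vector P of length N with entries in (0, 1).
#' @export
attention_pool <- function(h, wp) {
  h <- as.matrix(h)
  stopifnot(length(wp) == ncol(h))
  sigmoid(drop(h %*% wp))
}

#' Weighted prediction from node scores
#'
#' Computes contribution weights `A = softmax(W_A P)` and the prediction
#' `prob = sum_i A_i P_i`, a convex combination of the node scores.
#'
#' @param P node score vector of length N.
#' @param WA N x N prediction weight matrix.
#' @return List with `prob` (scalar in (0, 1)) and `weights` (A,
#'   non-negative, summing to 1).
#' @export
attention_predict <- function(P, WA) {
  WA <- as.matrix(WA)
  if (nrow(WA) != length(P) || ncol(WA) != length(P))
    stopf("WA must be N x N with N = length(P)")
  A <- softmax_vec(drop(WA %*% P))
  list(prob = sum(A * P), weights = A)
}

#' Average-pooling prediction
#'
#' The comparison head that replaces learned contribution weights with a
#' plain mean of the node scores: `prob = mean(P)`.
#'
#' @param P node score vector.
#' @return Scalar probability.
#' @export
gat_average_predict <- function(P) mean(P)

#' Dense softmax head on spliced node representations
#'
#' Flattens the node representation matrix row-major into one vector,
#' applies a leaky-ReLU dense layer and a two-class softmax output.
#'
#' @param h N x F' node representation matrix.
#' @param fc list with `W1` (units x N F'), `b1`, `W2` (2 x units), `b2`.
#' @param slope leaky ReLU slope.
#' @return Numeric vector of two class probabilities summing to 1
#'   (element 2 is the positive class).
#' @export
gat_fc_predict <- function(h, fc, slope = 0.2) {
  x <- as.numeric(t(as.matrix(h)))
  if (ncol(as.matrix(fc$W1)) != length(x)) stopf("fc$W1 width must equal N*F'")
  z1 <- drop(fc$W1 %*% x) + fc$b1
  h1 <- leaky_relu(z1, slope)
  z2 <- drop(fc$W2 %*% h1) + fc$b2
  softmax_vec(z2)
}

#' Learnable cluster-assignment pooling
#'
#' Pools a node feature map `Y` (N x C) with a cluster score column `S`
#' (N x 1) into the 1 x C map `S' Y` - the pooled representation of the
#' two-path learnable pooling comparison model. Exposed as a building
#' block; the surrounding two-path network is intentionally minimal and
#' experimental.
#'
#' @param Y N x C feature map.
#' @param S N x 1 cluster score matrix (or length-N vector).
#' @return 1 x C matrix.
#' @export
learn_pool <- function(Y, S) {
  Y <- as.matrix(Y)
  S <- as.matrix(S)
  if (ncol(S) != 1 || nrow(S) != nrow(Y))
    stopf("S must be N x 1 with N = nrow(Y)")
  t(S) %*% Y
}

#' Graph convolution layer (first-order or Chebyshev filter)
#'
#' First-order: symmetric degree-normalized propagation
#' `D^{-1/2} A D^{-1/2} h W'` followed by a leaky ReLU, where the weighted
#' adjacency `A` is assumed to carry self-loops. Chebyshev: the sum of
#' polynomial filter terms `T_k(Ltilde) h W_k'` of the scaled normalized
#' Laplacian (lambda_max approximated by 2) up to the given order.
#'
#' @param h N x F node feature matrix.
#' @param adj N x N symmetric non-negative adjacency with self-loops.
#' @param W units x F weight matrix (first-order), or list of `order + 1`
#'   such matrices (Chebyshev).
#' @param filter `"first_order"` or `"chebyshev"`.
#' @param order Chebyshev polynomial order (default 3).
#' @param slope leaky ReLU slope.
#' @return N x units representation matrix.
#' @export
gcn_layer <- function(h, adj, W, filter = c("first_order", "chebyshev"),
                      order = 3, slope = 0.2) {
  filter <- match.arg(filter)
  h <- as.matrix(h); adj <- as.matrix(adj)
  d <- rowSums(adj)
  if (any(d < 1e-12)) {
    warnf("zero-degree node under normalization; degree clamped")
    d[d < 1e-12] <- 1e-12
  }
  dn <- 1 / sqrt(d)
  M <- adj * outer(dn, dn)
  if (filter == "first_order") {
    leaky_relu(M %*% h %*% t(as.matrix(W)), slope)
  } else {
    stopifnot(is.list(W), length(W) == order + 1, order >= 1)
    Lt <- -M  # scaled Laplacian at lambda_max = 2
    Tk <- list(diag(nrow(adj)), Lt)
    if (order >= 2) for (k in 3:(order + 1)) Tk[[k]] <- 2 * Lt %*% Tk[[k - 1]] - Tk[[k - 2]]
    U <- Reduce(`+`, lapply(seq_len(order + 1), function(k)
      Tk[[k]] %*% h %*% t(as.matrix(W[[k]]))))
    leaky_relu(U, slope)
  }
}
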