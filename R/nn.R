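# Minimal dense / convolutional network engine for the vector- and
# image-input baseline models (MLP, CNN). Vectorized over minibatches;
# Adam optimizer; inverted dropout; early stopping on a validation set.

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    mh <- state$m[[i]] / (1 - b1^state$t)
    vh <- state$v[[i]] / (1 - b2^state$t)
    params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# --- multilayer perceptron ------------------------------------------------

mlp_init <- function(d_in, hidden, seed) {
  with_seed(seed, {
    dims <- c(d_in, hidden, 1)
    W <- list(); b <- list()
    for (i in seq_len(length(dims) - 1)) {
      W[[i]] <- glorot(dims[i + 1], dims[i])
      b[[i]] <- numeric(dims[i + 1])
    }
    list(W = W, b = b)
  })
}

# forward over a batch (rows = samples); returns caches for backward
mlp_forward <- function(p, X, dropout = 0, slope = 0.2, train = FALSE) {
  nh <- length(p$W) - 1
  H <- X; cache <- list(H0 = X)
  for (i in seq_len(nh)) {
    Z <- H %*% t(p$W[[i]]) + rep(p$b[[i]], each = nrow(H))
    A <- leaky_relu(Z, slope)
    if (train && dropout > 0) {
      mask <- matrix(runif(length(A)) >= dropout, nrow(A)) / (1 - dropout)
      A <- A * mask
      cache[[paste0("M", i)]] <- mask
    }
    cache[[paste0("Z", i)]] <- Z
    cache[[paste0("A", i)]] <- A
    H <- A
  }
  zout <- drop(H %*% t(p$W[[nh + 1]])) + p$b[[nh + 1]]
  cache$prob <- sigmoid(zout)
  cache
}

mlp_backward <- function(p, cache, y, dropout = 0, slope = 0.2) {
  nh <- length(p$W) - 1
  n <- length(y)
  dz <- matrix((cache$prob - y) / n, ncol = 1)  # BCE through sigmoid
  gW <- vector("list", nh + 1); gb <- vector("list", nh + 1)
  H <- cache[[paste0("A", nh)]]
  gW[[nh + 1]] <- t(dz) %*% H
  gb[[nh + 1]] <- sum(dz)
  dH <- dz %*% p$W[[nh + 1]]
  for (i in rev(seq_len(nh))) {
    if (!is.null(cache[[paste0("M", i)]])) dH <- dH * cache[[paste0("M", i)]]
    dZ <- dH * ifelse(cache[[paste0("Z", i)]] > 0, 1, slope)
    Hprev <- if (i == 1) cache$H0 else cache[[paste0("A", i - 1)]]
    gW[[i]] <- t(dZ) %*% Hprev
    gb[[i]] <- colSums(dZ)
    if (i > 1) dH <- dZ %*% p$W[[i]]
  }
  c(gW, gb)
}

mlp_fit <- function(X, y, Xval = NULL, yval = NULL, hidden = c(64, 32),
                    dropout = 0.5, learning_rate = 5e-4, batch_size = 10,
                    patience = 15, max_epochs = 300, seed = 1, slope = 0.2) {
  p <- mlp_init(ncol(X), hidden, seed)
  params <- c(p$W, p$b)
  nw <- length(p$W)
  st <- adam_new(params)
  n <- nrow(X)
  best <- list(err = Inf, params = params, epoch = 0L); wait <- 0L
  prev_err <- Inf
  with_seed(seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        pp <- list(W = params[seq_len(nw)], b = params[nw + seq_len(nw)])
        cache <- mlp_forward(pp, X[idx, , drop = FALSE], dropout, slope, train = TRUE)
        if (!all(is.finite(cache$prob))) stopf("non-finite MLP output at epoch %d", epoch)
        g <- mlp_backward(pp, cache, y[idx], dropout, slope)
        res <- adam_step(st, params, g, learning_rate)
        st <- res$state; params <- res$params
      }
      if (!is.null(Xval)) {
        pp <- list(W = params[seq_len(nw)], b = params[nw + seq_len(nw)])
        pv <- mlp_forward(pp, Xval, train = FALSE, slope = slope)$prob
        err <- mean((pv > 0.5) != (yval == 1))
        if (err < best$err) best <- list(err = err, params = params, epoch = epoch)
        if (err < prev_err) wait <- 0L else wait <- wait + 1L
        prev_err <- err
        if (wait >= patience) break
      }
    }
  })
  if (!is.null(Xval) && best$epoch > 0L) params <- best$params
  structure(list(W = params[seq_len(nw)], b = params[nw + seq_len(nw)],
                 hidden = hidden, slope = slope, dropout = dropout,
                 best_epoch = best$epoch),
            class = "gatnet_mlp")
}

mlp_predict <- function(fit, X) {
  mlp_forward(list(W = fit$W, b = fit$b), X, train = FALSE, slope = fit$slope)$prob
}

# --- small CNN ------------------------------------------------------------
# 3x3 valid convolutions, each followed by ReLU and 2x2 max pooling, then
# one ReLU dense layer and a two-class softmax.

conv_forward <- function(X, K, b) {
  # X: h x w x C x n; K: 9C x nk; returns oh x ow x nk x n plus im2col cache
  d <- dim(X); h <- d[1]; w <- d[2]; C <- d[3]; n <- d[4]
  oh <- h - 2; ow <- w - 2
  cols <- matrix(0, oh * ow * n, 9 * C)
  j <- 0
  for (dx in 0:2) for (dy in 0:2) {
    blk <- X[dy + seq_len(oh), dx + seq_len(ow), , , drop = FALSE]
    # -> (oh*ow) x C x n -> rows (pixel within sample, sample-major)
    blk <- aperm(blk, c(1, 2, 4, 3))              # oh ow n C
    cols[, j * C + seq_len(C)] <- matrix(blk, oh * ow * n, C)
    j <- j + 1
  }
  out <- cols %*% K
  out <- sweep(out, 2, b, `+`)
  list(out = array(aperm(array(out, c(oh, ow, n, ncol(K))), c(1, 2, 4, 3)),
                   c(oh, ow, ncol(K), n)),
       cols = cols, in_dim = d)
}

conv_backward <- function(cache, K, dOut) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]; C <- d[3]; n <- d[4]
  oh <- h - 2; ow <- w - 2; nk <- ncol(K)
  dmat <- matrix(aperm(dOut, c(1, 2, 4, 3)), oh * ow * n, nk)
  gK <- t(cache$cols) %*% dmat
  gb <- colSums(dmat)
  dcols <- dmat %*% t(K)
  dX <- array(0, d)
  j <- 0
  for (dx in 0:2) for (dy in 0:2) {
    blk <- array(dcols[, j * C + seq_len(C)], c(oh, ow, n, C))
    dX[dy + seq_len(oh), dx + seq_len(ow), , ] <-
      dX[dy + seq_len(oh), dx + seq_len(ow), , , drop = FALSE] +
      aperm(blk, c(1, 2, 4, 3))
    j <- j + 1
  }
  list(gK = gK, gb = gb, dX = dX)
}

maxpool_forward <- function(X) {
  d <- dim(X); oh <- d[1] %/% 2; ow <- d[2] %/% 2
  i1 <- seq_len(oh) * 2 - 1; i2 <- seq_len(ow) * 2 - 1
  cand <- array(0, c(oh, ow, d[3], d[4], 4))
  cand[, , , , 1] <- X[i1, i2, , , drop = FALSE]
  cand[, , , , 2] <- X[i1 + 1, i2, , , drop = FALSE]
  cand[, , , , 3] <- X[i1, i2 + 1, , , drop = FALSE]
  cand[, , , , 4] <- X[i1 + 1, i2 + 1, , , drop = FALSE]
  flat <- matrix(cand, oh * ow * d[3] * d[4], 4)
  out <- array(pmax(flat[, 1], flat[, 2], flat[, 3], flat[, 4]),
               c(oh, ow, d[3], d[4]))
  # argmax per pooled cell (ties -> first, deterministic)
  amax <- max.col(flat, ties.method = "first")
  list(out = out, amax = amax, in_dim = d)
}

maxpool_backward <- function(cache, dOut) {
  d <- cache$in_dim; oh <- d[1] %/% 2; ow <- d[2] %/% 2
  dX <- array(0, d)
  # scatter each pooled gradient to its argmax position
  idx <- arrayInd(seq_along(dOut), c(oh, ow, d[3], d[4]))
  a <- cache$amax
  ry <- (a == 2L | a == 4L)
  rx <- (a == 3L | a == 4L)
  pos <- cbind(idx[, 1] * 2 - 1 + ry, idx[, 2] * 2 - 1 + rx, idx[, 3], idx[, 4])
  dX[pos] <- dX[pos] + as.numeric(dOut)
  dX
}

cnn_init <- function(h, w, kernels, fc_units, seed) {
  with_seed(seed, {
    params <- list()
    C <- 1
    for (k in kernels) {
      params[[length(params) + 1]] <- glorot(9 * C, k)   # conv kernel
      params[[length(params) + 1]] <- numeric(k)         # conv bias
      h <- (h - 2) %/% 2; w <- (w - 2) %/% 2
      C <- k
    }
    flat <- h * w * C
    if (flat < 1) stopf("input too small for three conv/pool blocks")
    params[[length(params) + 1]] <- glorot(fc_units, flat)
    params[[length(params) + 1]] <- numeric(fc_units)
    params[[length(params) + 1]] <- glorot(2, fc_units)
    params[[length(params) + 1]] <- numeric(2)
    params
  })
}

cnn_forward <- function(params, X, kernels) {
  caches <- list()
  H <- X
  for (i in seq_along(kernels)) {
    cv <- conv_forward(H, params[[2 * i - 1]], params[[2 * i]])
    A <- pmax(cv$out, 0)
    mp <- maxpool_forward(A)
    caches[[i]] <- list(conv = cv, relu = cv$out, pool = mp)
    H <- mp$out
  }
  d <- dim(H); n <- d[4]
  flat <- t(matrix(H, prod(d[1:3]), n))
  i0 <- 2 * length(kernels)
  Z1 <- flat %*% t(params[[i0 + 1]]) + rep(params[[i0 + 2]], each = n)
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% t(params[[i0 + 3]]) + rep(params[[i0 + 4]], each = n)
  Z2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Z2) / rowSums(exp(Z2))
  list(caches = caches, flat = flat, Z1 = Z1, A1 = A1, P = P,
       pooled_dim = d)
}

cnn_backward <- function(params, fw, y, kernels) {
  n <- length(y)
  dZ2 <- fw$P
  dZ2[cbind(seq_len(n), y + 1)] <- dZ2[cbind(seq_len(n), y + 1)] - 1
  dZ2 <- dZ2 / n
  i0 <- 2 * length(kernels)
  g <- vector("list", length(params))
  g[[i0 + 3]] <- t(dZ2) %*% fw$A1
  g[[i0 + 4]] <- colSums(dZ2)
  dA1 <- dZ2 %*% params[[i0 + 3]]
  dZ1 <- dA1 * (fw$Z1 > 0)
  g[[i0 + 1]] <- t(dZ1) %*% fw$flat
  g[[i0 + 2]] <- colSums(dZ1)
  dflat <- dZ1 %*% params[[i0 + 1]]
  dH <- array(t(dflat), fw$pooled_dim)
  for (i in rev(seq_along(kernels))) {
    cc <- fw$caches[[i]]
    dA <- maxpool_backward(cc$pool, dH)
    dConv <- dA * (cc$relu > 0)
    cb <- conv_backward(cc$conv, params[[2 * i - 1]], dConv)
    g[[2 * i - 1]] <- cb$gK
    g[[2 * i]] <- cb$gb
    dH <- cb$dX
  }
  g
}

cnn_fit <- function(X, y, Xval = NULL, yval = NULL, kernels = c(16, 32, 64),
                    fc_units = 1024, learning_rate = 1e-4, batch_size = 10,
                    patience = 15, max_epochs = 100, seed = 1) {
  # X: h x w x n matrices (one input channel)
  d <- dim(X)
  Xc <- array(X, c(d[1], d[2], 1, d[3]))
  if (!is.null(Xval)) {
    dv <- dim(Xval)
    Xvc <- array(Xval, c(dv[1], dv[2], 1, dv[3]))
  }
  params <- cnn_init(d[1], d[2], kernels, fc_units, seed)
  st <- adam_new(params)
  n <- d[3]
  best <- list(err = Inf, params = params, epoch = 0L); wait <- 0L
  prev_err <- Inf
  with_seed(seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        fw <- cnn_forward(params, Xc[, , , idx, drop = FALSE], kernels)
        if (!all(is.finite(fw$P))) stopf("non-finite CNN output at epoch %d", epoch)
        g <- cnn_backward(params, fw, y[idx], kernels)
        res <- adam_step(st, params, g, learning_rate)
        st <- res$state; params <- res$params
      }
      if (!is.null(Xval)) {
        pv <- cnn_forward(params, Xvc, kernels)$P[, 2]
        err <- mean((pv > 0.5) != (yval == 1))
        if (err < best$err) best <- list(err = err, params = params, epoch = epoch)
        if (err < prev_err) wait <- 0L else wait <- wait + 1L
        prev_err <- err
        if (wait >= patience) break
      }
    }
  })
  if (!is.null(Xval) && best$epoch > 0L) params <- best$params
  structure(list(params = params, kernels = kernels, best_epoch = best$epoch),
            class = "gatnet_cnn")
}

cnn_predict <- function(fit, X) {
  d <- dim(X)
  Xc <- array(X, c(d[1], d[2], 1, d[3]))
  cnn_forward(fit$params, Xc, fit$kernels)$P[, 2]
}
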