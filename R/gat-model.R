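#' Model configuration for the graph classifiers
#'
#' Assembles the architecture description shared by the fitting, prediction
#' and interpretation code. The canonical attention-pooling classifier
#' ("gat2") stacks multi-head graph attention layers (concatenated heads on
#' hidden layers, averaged heads on the last), maps each node
#' representation to a score \eqn{P_i = \sigma(W^p h'_i)}, forms
#' contribution weights \eqn{A = softmax(W^A P)} and predicts
#' \eqn{prob = \sum_i A_i P_i}. Comparison variants swap the head
#' (average pooling; dense softmax on spliced node vectors) or the node
#' learner (GCN first-order / Chebyshev filters feeding the same
#' pooling-and-prediction part).
#'
#' @param n_nodes number of graph nodes N.
#' @param in_dim node feature dimension F (equal to N for connectivity
#'   graphs).
#' @param model one of `"gat2"`, `"gat_average"`, `"gat_fc"`,
#'   `"gcn_at_1st"`, `"gcn_at_cheby"`.
#' @param heads attention heads per layer (default `c(5, 3)`).
#' @param units output units per layer (default `c(24, 3)`).
#' @param combine per-layer head combination, `"concat"` or `"average"`;
#'   default concatenates on hidden layers and averages on the last.
#' @param activation per-layer activation, `"leaky_relu"`, `"sigmoid"` or
#'   `"identity"`. The default is sigmoid on every layer: the layer
#'   equations define their activation as the logistic function, while the
#'   leaky ReLU acts inside the attention scores.
#' @param gcn_units units of the GCN node learner (default 24).
#' @param cheby_order Chebyshev polynomial order (default 3).
#' @param fc_units units of the dense head (default 64).
#' @param lrelu_slope negative slope of leaky ReLU activations (default 0.2).
#' @param attn_slope negative slope inside the attention score (default 0.2).
#' @param edge_weighted_attention if `TRUE`, attention coefficients are
#'   additionally multiplied by the (renormalized) edge weights, via a
#'   log-weight prior added to the attention scores. Default `FALSE`:
#'   edge weights shape the graph structure only. Exploratory.
#' @return A `gat_config` list understood by [gat_network()] and
#'   [gat_fit()].
#' @export
gat_config <- function(n_nodes, in_dim = n_nodes,
                       model = c("gat2", "gat_average", "gat_fc",
                                 "gcn_at_1st", "gcn_at_cheby"),
                       heads = c(5, 3), units = c(24, 3),
                       combine = NULL, activation = NULL,
                       gcn_units = 24, cheby_order = 3, fc_units = 64,
                       lrelu_slope = 0.2, attn_slope = 0.2,
                       edge_weighted_attention = FALSE) {
  model <- match.arg(model)
  head <- switch(model, gat2 = "attention", gcn_at_1st = "attention",
                 gcn_at_cheby = "attention", gat_average = "average",
                 gat_fc = "fc")
  learner <- switch(model, gcn_at_1st = "gcn1", gcn_at_cheby = "gcncheb", "gat")
  nl <- length(heads)
  if (learner == "gat") {
    if (length(units) != nl) stopf("heads and units must have equal length")
    if (is.null(combine))
      combine <- c(rep("concat", nl - 1), "average")
    # sigma in the layer equations is the sigmoid; the leaky ReLU lives
    # inside the attention scores. Override via `activation` to explore.
    if (is.null(activation))
      activation <- rep("sigmoid", nl)
    combine <- match.arg(combine, c("concat", "average"), several.ok = TRUE)
    activation <- match.arg(activation, c("leaky_relu", "sigmoid", "identity"),
                            several.ok = TRUE)
    stopifnot(length(combine) == nl, length(activation) == nl)
  }
  structure(list(
    n_nodes = as.integer(n_nodes), in_dim = as.integer(in_dim),
    model = model, node_learner = learner, head = head,
    heads = as.integer(heads), units = as.integer(units),
    combine = if (learner == "gat") match(combine, c("concat", "average")) - 1L else integer(),
    combine_str = if (learner == "gat") combine else character(),
    activation = if (learner == "gat")
      match(activation, c("leaky_relu", "sigmoid", "identity")) - 1L else integer(),
    activation_str = if (learner == "gat") activation else character(),
    gcn_units = as.integer(gcn_units), cheby_order = as.integer(cheby_order),
    fc_units = as.integer(fc_units),
    lrelu_slope = lrelu_slope, attn_slope = attn_slope,
    edge_weighted_attention = isTRUE(edge_weighted_attention)
  ), class = "gat_config")
}

# width of the node representations entering the head
config_f_last <- function(cfg) {
  if (cfg$node_learner != "gat") return(cfg$gcn_units)
  f <- cfg$in_dim
  for (l in seq_along(cfg$heads))
    f <- if (cfg$combine[l] == 0L) cfg$heads[l] * cfg$units[l] else cfg$units[l]
  f
}

#' Parameter layout of a model configuration
#'
#' Describes every learnable tensor (name, shape, offset into the flat
#' parameter vector) in the order the computational engine expects.
#'
#' @param cfg a `gat_config`.
#' @return Data frame with columns `name`, `nrow`, `ncol`, `offset`
#'   (1-based start in the flat vector).
#' @export
gat_param_layout <- function(cfg) {
  rows <- list()
  add <- function(name, nr, nc) rows[[length(rows) + 1]] <<- list(name, nr, nc)
  if (cfg$node_learner == "gat") {
    f_in <- cfg$in_dim
    for (l in seq_along(cfg$heads)) {
      for (k in seq_len(cfg$heads[l])) {
        add(sprintf("W_l%d_h%d", l, k), cfg$units[l], f_in)
        add(sprintf("a_l%d_h%d", l, k), 2L * cfg$units[l], 1L)
      }
      f_in <- if (cfg$combine[l] == 0L) cfg$heads[l] * cfg$units[l] else cfg$units[l]
    }
  } else {
    nk <- if (cfg$node_learner == "gcn1") 1L else cfg$cheby_order + 1L
    for (k in seq_len(nk)) add(sprintf("Wg_%d", k - 1L), cfg$gcn_units, cfg$in_dim)
  }
  fl <- config_f_last(cfg)
  if (cfg$head %in% c("attention", "average")) {
    add("wp", fl, 1L)
    if (cfg$head == "attention") add("WA", cfg$n_nodes, cfg$n_nodes)
  } else {
    add("W_fc1", cfg$fc_units, cfg$n_nodes * fl)
    add("b_fc1", cfg$fc_units, 1L)
    add("W_fc2", 2L, cfg$fc_units)
    add("b_fc2", 2L, 1L)
  }
  nm <- vapply(rows, `[[`, "", 1)
  nr <- vapply(rows, `[[`, 1L, 2)
  nc <- vapply(rows, `[[`, 1L, 3)
  sz <- nr * nc
  data.frame(name = nm, nrow = nr, ncol = nc,
             offset = cumsum(c(1L, head(sz, -1L))))
}

# scaled uniform fan-based initialization (bias tensors start at zero)
init_theta <- function(cfg, seed = 1) {
  lay <- gat_param_layout(cfg)
  with_seed(seed, {
    theta <- numeric(sum(lay$nrow * lay$ncol))
    for (i in seq_len(nrow(lay))) {
      n <- lay$nrow[i] * lay$ncol[i]
      idx <- lay$offset[i]:(lay$offset[i] + n - 1)
      if (startsWith(lay$name[i], "b_")) {
        theta[idx] <- 0
      } else {
        fan_in <- if (lay$ncol[i] == 1L) lay$nrow[i] else lay$ncol[i]
        fan_out <- if (lay$ncol[i] == 1L) 1L else lay$nrow[i]
        lim <- sqrt(6 / (fan_in + fan_out))
        theta[idx] <- runif(n, -lim, lim)
      }
    }
    theta
  })
}

cfg_for_cpp <- function(cfg) {
  list(n_nodes = cfg$n_nodes, in_dim = cfg$in_dim,
       node_learner = cfg$node_learner, head = cfg$head,
       heads = cfg$heads, units = cfg$units, combine = cfg$combine,
       activation = cfg$activation, gcn_units = cfg$gcn_units,
       cheby_order = cfg$cheby_order, fc_units = cfg$fc_units,
       lrelu_slope = cfg$lrelu_slope, attn_slope = cfg$attn_slope,
       edge_weighted_attention = cfg$edge_weighted_attention)
}

#' Construct an (untrained) graph network model
#'
#' @param cfg a [gat_config()].
#' @param seed seed for the fan-scaled uniform weight initialization.
#' @param theta optional explicit flat parameter vector (overrides `seed`).
#' @return A `gatnet` object; see [gat_fit()] for the trained variant.
#' @export
gat_network <- function(cfg, seed = 1, theta = NULL) {
  stopifnot(inherits(cfg, "gat_config"))
  lay <- gat_param_layout(cfg)
  want <- sum(lay$nrow * lay$ncol)
  stopifnot(want == cpp_theta_length(cfg_for_cpp(cfg)))
  if (is.null(theta)) theta <- init_theta(cfg, seed)
  if (length(theta) != want)
    stopf("theta has length %d, expected %d", length(theta), want)
  structure(list(config = cfg, theta = as.numeric(theta), layout = lay,
                 trained = FALSE, history = NULL),
            class = "gatnet")
}

#' @export
coef.gatnet <- function(object, ...) {
  lay <- object$layout
  out <- lapply(seq_len(nrow(lay)), function(i) {
    n <- lay$nrow[i] * lay$ncol[i]
    m <- matrix(object$theta[lay$offset[i]:(lay$offset[i] + n - 1)],
                lay$nrow[i], lay$ncol[i])
    if (lay$ncol[i] == 1L) drop(m) else m
  })
  names(out) <- lay$name
  out
}

#' Replace the parameters of a graph network model
#'
#' @param model a `gatnet`.
#' @param params named list matching the `coef()` output (column-major
#'   flattening), or a flat numeric vector.
#' @return The model with parameters replaced.
#' @export
set_coef <- function(model, params) {
  stopifnot(inherits(model, "gatnet"))
  lay <- model$layout
  if (is.numeric(params) && is.null(names(params))) {
    stopifnot(length(params) == length(model$theta))
    model$theta <- as.numeric(params)
    return(model)
  }
  theta <- model$theta
  for (nm in names(params)) {
    i <- match(nm, lay$name)
    if (is.na(i)) stopf("unknown parameter tensor '%s'", nm)
    v <- as.numeric(params[[nm]])
    n <- lay$nrow[i] * lay$ncol[i]
    if (length(v) != n) stopf("tensor '%s' has %d values, expected %d", nm, length(v), n)
    theta[lay$offset[i]:(lay$offset[i] + n - 1)] <- v
  }
  model$theta <- theta
  model
}

dataset_arrays <- function(dataset) {
  stopifnot(inherits(dataset, "graph_dataset"))
  B <- length(dataset)
  N <- nrow(dataset[[1]]$features)
  Fd <- ncol(dataset[[1]]$features)
  X <- array(0, dim = c(N, Fd, B))
  A <- array(0, dim = c(N, N, B))
  for (b in seq_len(B)) {
    X[, , b] <- dataset[[b]]$features
    A[, , b] <- dataset[[b]]$adj
  }
  list(X = X, A = A, y = dataset_labels(dataset))
}

#' Training control parameters
#'
#' @param learning_rate Adam step size (default 1e-4, the setting used for
#'   all graph models here).
#' @param batch_size minibatch size (default 10).
#' @param patience early-stopping patience: training halts once the
#'   monitored error rate has gone this many consecutive epochs without
#'   decreasing from one epoch to the next (default 15). The parameters
#'   of the best monitored epoch are kept (see `restore_best`).
#' @param max_epochs hard epoch cap (default 500).
#' @param seed seed driving initialization and minibatch shuffling.
#' @param restore_best keep the parameters of the best monitored epoch
#'   (default `TRUE`).
#' @param verbose print per-epoch progress.
#' @return A list of class `gat_control`.
#' @export
gat_control <- function(learning_rate = 1e-4, batch_size = 10, patience = 15,
                        max_epochs = 500, seed = 1, restore_best = TRUE,
                        verbose = FALSE) {
  stopifnot(patience >= 1, max_epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs, seed = seed,
                 restore_best = restore_best, verbose = verbose),
            class = "gat_control")
}

#' Fit a graph attention (or graph convolution) classifier
#'
#' Trains the selected model with Adam on the binary cross-entropy loss,
#' looping graphs in minibatches. When a validation set is supplied,
#' training stops early once its error rate has not strictly decreased for
#' `control$patience` consecutive epochs, and the parameters of the best
#' validation epoch are restored.
#'
#' @param dataset a `graph_dataset` of training graphs.
#' @param model architecture, see [gat_config()].
#' @param heads,units per-layer attention heads and units. Defaults are the
#'   connectome-shaped setting `c(5, 3)` / `c(24, 3)`; the larger synthetic
#'   benchmark uses `c(4, 4)` / `c(16, 16)`.
#' @param validation optional `graph_dataset` monitored for early stopping.
#' @param control a [gat_control()].
#' @param config optional pre-built [gat_config()] (overrides `model`,
#'   `heads`, `units` and `...`).
#' @param ... further arguments to [gat_config()].
#' @return A trained `gatnet` with elements `config`, `theta`, `history`
#'   (per-epoch train loss/error and validation error), `best_epoch`, and
#'   `n_epochs`. Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' \donttest{
#' d <- synthetic_graphs(n_graphs = 60, n_nodes = 10, n_selected = 5, seed = 1)
#' fit <- gat_fit(d[1:40], model = "gat2", heads = c(2, 2), units = c(4, 4),
#'                validation = d[41:60],
#'                control = gat_control(max_epochs = 5, learning_rate = 1e-3))
#' predict(fit, d[41:60])[1:5]
#' }
#' @export
gat_fit <- function(dataset, model = "gat2", heads = c(5, 3), units = c(24, 3),
                    validation = NULL, control = gat_control(),
                    config = NULL, ...) {
  stopifnot(inherits(dataset, "graph_dataset"))
  tr <- dataset_arrays(dataset)
  if (is.null(config)) {
    config <- gat_config(n_nodes = dim(tr$X)[1], in_dim = dim(tr$X)[2],
                         model = model, heads = heads, units = units, ...)
  }
  ccfg <- cfg_for_cpp(config)
  va <- if (!is.null(validation)) dataset_arrays(validation)
  net <- gat_network(config, seed = control$seed)
  theta <- net$theta

  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  B <- length(dataset)
  bs <- min(control$batch_size, B)
  best_err <- Inf; best_theta <- theta; best_epoch <- 0L; wait <- 0L
  prev_err <- Inf
  hist <- list()

  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(B)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, B, by = bs)) {
        idx <- ord[start:min(start + bs - 1, B)]
        res <- cpp_batch(tr$X[, , idx, drop = FALSE],
                         tr$A[, , idx, drop = FALSE],
                         tr$y[idx], ccfg, theta, grad = TRUE)
        if (!is.finite(res$loss))
          stopf("non-finite loss at epoch %d (divergent optimization)", epoch)
        ep_loss <- ep_loss + res$loss
        ep_correct <- ep_correct + sum((res$probs > 0.5) == (tr$y[idx] == 1))
        gr <- as.numeric(res$grad) / length(idx)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * gr
        v <- b2 * v + (1 - b2) * gr^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - control$learning_rate * mhat / (sqrt(vhat) + eps)
        if (!all(is.finite(theta)))
          stopf("non-finite parameters at epoch %d (divergent optimization)", epoch)
      }
      val_err <- NA_real_
      if (!is.null(va)) {
        pv <- cpp_batch(va$X, va$A, va$y, ccfg, theta)$probs
        val_err <- mean((pv > 0.5) != (va$y == 1))
      }
      hist[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / B,
                         train_error = 1 - ep_correct / B, val_error = val_err)
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.4f  train err %.4f  val err %s",
                        epoch, ep_loss / B, 1 - ep_correct / B,
                        ifelse(is.na(val_err), "-", sprintf("%.4f", val_err))))
      if (!is.null(va)) {
        if (val_err < best_err) {
          best_err <- val_err; best_theta <- theta; best_epoch <- epoch
        }
        # stop once the monitored error has not decreased from one round
        # to the next for `patience` consecutive rounds
        if (val_err < prev_err) wait <- 0L else wait <- wait + 1L
        prev_err <- val_err
        if (wait >= control$patience) break
      }
    }
  })

  if (!is.null(va) && control$restore_best && best_epoch > 0L) {
    net$theta <- best_theta
  } else {
    net$theta <- theta
    best_epoch <- length(hist)
  }
  net$trained <- TRUE
  net$history <- do.call(rbind.data.frame, lapply(hist, as.list))
  net$best_epoch <- best_epoch
  net$n_epochs <- length(hist)
  net$control <- control
  net$val_error <- if (is.null(va)) NA_real_ else best_err
  net
}

#' Predict from a fitted graph network
#'
#' @param object a `gatnet`.
#' @param newdata a `graph_dataset` (or single `graph_sample`).
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   0/1 labels at threshold 0.5, `"detail"` for a per-graph list with node
#'   scores, contribution weights and attention matrices.
#' @param ... unused.
#' @return Numeric vector (prob/class) or list of lists (detail).
#' @export
predict.gatnet <- function(object, newdata, type = c("prob", "class", "detail"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "graph_sample")) newdata <- as_graph_dataset(list(newdata))
  da <- dataset_arrays(newdata)
  ccfg <- cfg_for_cpp(object$config)
  if (type == "detail") {
    return(lapply(seq_len(dim(da$X)[3]), function(b)
      cpp_forward_detail(da$X[, , b], da$A[, , b], ccfg, object$theta)))
  }
  probs <- as.numeric(cpp_batch(da$X, da$A, rep(-1L, dim(da$X)[3]),
                                ccfg, object$theta)$probs)
  if (type == "class") as.integer(probs > 0.5) else probs
}

# mean loss and input gradients for interpretation code
model_input_gradients <- function(object, dataset) {
  da <- dataset_arrays(dataset)
  res <- cpp_batch(da$X, da$A, da$y, cfg_for_cpp(object$config), object$theta,
                   grad = FALSE, input_grad = TRUE)
  list(probs = as.numeric(res$probs), loss = res$loss, grads = res$input_grad,
       X = da$X, y = da$y)
}

#' @export
print.gatnet <- function(x, ...) {
  cfg <- x$config
  arch <- if (cfg$node_learner == "gat")
    sprintf("GAT layers [heads %s; units %s; %s]",
            paste(cfg$heads, collapse = ","), paste(cfg$units, collapse = ","),
            paste(cfg$combine_str, collapse = ","))
  else sprintf("GCN (%s, %d units%s)", cfg$node_learner, cfg$gcn_units,
               if (cfg$node_learner == "gcncheb")
                 sprintf(", order %d", cfg$cheby_order) else "")
  cat(sprintf("gatnet model '%s': %s -> %s head; %d nodes, %d parameters%s\n",
              cfg$model, arch, cfg$head, cfg$n_nodes, length(x$theta),
              if (isTRUE(x$trained)) sprintf("; trained %d epochs (best %d)",
                                             x$n_epochs, x$best_epoch)
              else " (untrained)"))
  invisible(x)
}

#' @export
summary.gatnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("final train loss %.4f; best validation error %s\n",
                h$train_loss[nrow(h)],
                ifelse(is.na(object$val_error), "-",
                       sprintf("%.4f (epoch %d)", object$val_error,
                               object$best_epoch))))
  }
  invisible(object)
}

#' Plot training history of a fitted graph network
#'
#' @param x a trained `gatnet`.
#' @param ... passed to [plot.default()].
#' @export
plot.gatnet <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stopf("model has no training history")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss / error",
       ylim = range(c(h$train_loss, h$train_error, h$val_error), na.rm = TRUE),
       ...)
  graphics::lines(h$epoch, h$train_error, lty = 2)
  if (any(!is.na(h$val_error))) {
    graphics::lines(h$epoch, h$val_error, lty = 3)
    graphics::abline(v = x$best_epoch, col = "grey")
  }
  graphics::legend("topright", c("train loss", "train error", "val error"),
                   lty = 1:3, bty = "n")
  invisible(x)
}
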