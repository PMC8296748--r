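#' Learn a global node-feature importance mask
#'
#' Learns one N x F mask shared by all provided samples by gradient descent
#' on the model's classification loss evaluated at `mask * features`
#' (elementwise), plus sparsity penalties: an L1 term on the mask values
#' and an element-wise entropy term that pushes entries toward 0 or 1. The
#' mask is sigmoid-parameterized, so its entries stay in `[0, 1]` at every
#' step; entries near zero flag features the trained model does not need.
#'
#' @param model a trained `gatnet`.
#' @param dataset a `graph_dataset` of samples to explain (at least 1).
#' @param steps optimization steps (default 200).
#' @param learning_rate Adam step size for the mask (default 1e-2).
#' @param l1 L1 sparsity coefficient (default 1e-4). The defaults keep
#'   both penalties well below the model-loss gradients: under Adam's
#'   per-coordinate normalization a dominating penalty term moves every
#'   entry identically and erases the importance signal.
#' @param entropy entropy coefficient pushing entries toward 0/1
#'   (default 0: above the sigmoid midpoint this term pushes upward, so
#'   whenever it outweighs `l1` any entry nudged past the midpoint runs
#'   away to 1 and pollutes the top of the ranking).
#' @param init_noise sd of the noise added to the pre-squash
#'   initialization at 1.0 (default 0.05).
#' @param per_class if `TRUE`, learn one mask per class and return their
#'   list; default one global mask.
#' @param seed seed for the mask initialization.
#' @return A `feature_mask`: N x F matrix in `[0, 1]` (or a list of two for
#'   `per_class`), with the optimization loss trace as attribute
#'   `history`.
#' @export
learn_feature_mask <- function(model, dataset, steps = 200,
                               learning_rate = 1e-2, l1 = 1e-4,
                               entropy = 0, init_noise = 0.05,
                               per_class = FALSE, seed = 1) {
  stopifnot(inherits(model, "gatnet"), inherits(dataset, "graph_dataset"),
            length(dataset) >= 1)
  if (per_class) {
    y <- dataset_labels(dataset)
    out <- lapply(c(0, 1), function(cl)
      learn_feature_mask(model, dataset[y == cl], steps, learning_rate,
                         l1, entropy, init_noise, FALSE, seed))
    names(out) <- c("class0", "class1")
    return(out)
  }
  da <- dataset_arrays(dataset)
  N <- dim(da$X)[1]; Fd <- dim(da$X)[2]; B <- dim(da$X)[3]
  ccfg <- cfg_for_cpp(model$config)
  logits <- with_seed(seed, matrix(1 + rnorm(N * Fd, sd = init_noise), N, Fd))
  m1 <- v1 <- matrix(0, N, Fd); b1 <- 0.9; b2 <- 0.999
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    mk <- sigmoid(logits)
    Xm <- da$X * as.numeric(mk)   # mask recycled over the sample slices
    res <- cpp_batch(Xm, da$A, da$y, ccfg, model$theta,
                     grad = FALSE, input_grad = TRUE)
    if (!is.finite(res$loss)) stopf("non-finite loss in mask optimization (step %d)", s)
    # d(model loss)/d(mask) summed over samples
    gm <- apply(res$input_grad * da$X, c(1, 2), sum) / B
    mc <- pmin(pmax(mk, 1e-12), 1 - 1e-12)
    # d/dm of the element-wise entropy penalty is -logit(m)
    pen <- l1 * sign(mk) - entropy * (log(mc) - log(1 - mc))
    g <- (gm + pen) * mk * (1 - mk)
    hist[s] <- res$loss / B + l1 * mean(abs(mk)) -
      entropy * mean(mc * log(mc) + (1 - mc) * log(1 - mc))
    m1 <- b1 * m1 + (1 - b1) * g
    v1 <- b2 * v1 + (1 - b2) * g^2
    logits <- logits - learning_rate * (m1 / (1 - b1^s)) /
      (sqrt(v1 / (1 - b2^s)) + 1e-8)
  }
  structure(sigmoid(logits), class = c("feature_mask", "matrix", "array"),
            history = hist)
}

#' Gradient saliency of the input features
#'
#' Computes the gradient of the model loss with respect to every input
#' feature of every sample, averages the gradients across samples first
#' and takes absolute values second (the alternative order - mean of
#' absolute gradients - is available via `average_before_abs = FALSE`).
#'
#' @param model a trained `gatnet`.
#' @param dataset a `graph_dataset`.
#' @param average_before_abs average gradients across samples before
#'   taking the absolute value (default `TRUE`).
#' @return A `feature_ranking` (see [rank_features()]) with the N x F
#'   score matrix as attribute `scores`.
#' @export
saliency <- function(model, dataset, average_before_abs = TRUE) {
  gi <- model_input_gradients(model, dataset)
  score <- if (average_before_abs) abs(apply(gi$grads, c(1, 2), mean))
           else apply(abs(gi$grads), c(1, 2), mean)
  rank_features(score)
}

#' Rank node-feature entries by importance score
#'
#' Produces the deterministic ordering used for feature hacking: scores
#' descending, ties broken by node index then feature index.
#'
#' @param scores N x F matrix of non-negative importance values
#'   (a [learn_feature_mask()] result or a saliency score matrix).
#' @return A `feature_ranking` data frame with columns `node`, `feature`,
#'   `score`, ordered by decreasing score; the input matrix is kept as
#'   attribute `scores`.
#' @export
rank_features <- function(scores) {
  scores <- unclass(as.matrix(scores))
  idx <- expand.grid(node = seq_len(nrow(scores)), feature = seq_len(ncol(scores)))
  idx$score <- scores[cbind(idx$node, idx$feature)]
  ord <- order(-idx$score, idx$node, idx$feature)
  structure(idx[ord, , drop = FALSE], row.names = seq_len(nrow(idx)),
            class = c("feature_ranking", "data.frame"), scores = scores)
}

#' Zero out the top-ranked node features of every sample
#'
#' Sets the top-k (node, feature) entries of each sample's node-feature
#' matrix to zero; adjacency (graph structure) is untouched, and the input
#' dataset is not modified.
#'
#' @param dataset a `graph_dataset`.
#' @param ranking a `feature_ranking` (or data frame with `node`,
#'   `feature` columns in rank order).
#' @param k number of entries to zero (0 <= k <= N*F).
#' @return A new `graph_dataset` with perturbed features.
#' @export
hack_features <- function(dataset, ranking, k) {
  stopifnot(inherits(dataset, "graph_dataset"))
  if (k < 0) stopf("k must be non-negative")
  nf <- nrow(dataset[[1]]$features) * ncol(dataset[[1]]$features)
  if (k > nf) stopf("k = %d exceeds the %d node-feature entries", k, nf)
  if (k == 0) return(dataset)
  pos <- cbind(ranking$node[seq_len(k)], ranking$feature[seq_len(k)])
  out <- lapply(dataset, function(g) {
    g$features[pos] <- 0
    g
  })
  attributes(out) <- attributes(dataset)
  out
}

#' Evaluate an explanation by feature perturbation
#'
#' For each requested k, zeroes the top-k ranked features of every sample
#' and measures: CPP, the mean absolute change of the predicted
#' positive-class probability; NLCI, the number of samples whose
#' 0.5-thresholded label flips; and the full metric suite on the perturbed
#' samples.
#'
#' @param model a trained `gatnet`.
#' @param dataset held-out samples to perturb.
#' @param ranking a `feature_ranking`.
#' @param ks vector of perturbation sizes.
#' @return A `perturbation_report` data frame with one row per k:
#'   `k`, `cpp`, `nlci`, and the metric columns after perturbation.
#' @export
perturb_evaluate <- function(model, dataset, ranking, ks) {
  y <- dataset_labels(dataset)
  p0 <- predict(model, dataset)
  rows <- lapply(ks, function(k) {
    pk <- predict(model, hack_features(dataset, ranking, k))
    c(k = k, cpp = mean(abs(pk - p0)),
      nlci = sum((pk > 0.5) != (p0 > 0.5)),
      classification_metrics(y, pk))
  })
  structure(as.data.frame(do.call(rbind, rows)),
            class = c("perturbation_report", "data.frame"))
}

#' Group statistics of the top-ranked connections
#'
#' Collapses the symmetric (i, j)/(j, i) mask entries of off-diagonal
#' connections to one connection score (their average), takes the top
#' `top_n` connections, and for each reports the per-group mean of the
#' signed feature value, the mean difference, and an independent
#' two-sample t-test p-value (Welch by default).
#'
#' @param dataset a `graph_dataset` containing both classes.
#' @param scores N x F importance matrix (mask or saliency scores).
#' @param top_n number of connections to report (default 10).
#' @param var_equal use the pooled-variance (Student) t-test instead of
#'   Welch (default `FALSE`).
#' @return Data frame with columns `node_i`, `node_j`, `score`,
#'   `mean_class1`, `mean_class0`, `difference`, `p_value` (NA when a
#'   group has fewer than 2 samples or zero variance makes the test
#'   degenerate, except the equal-constants case which yields p = 1 when
#'   the difference is 0 and p = 0 otherwise by convention).
#' @export
top_connections <- function(dataset, scores, top_n = 10, var_equal = FALSE) {
  scores <- attr(scores, "scores") %||% unclass(as.matrix(scores))
  N <- nrow(scores)
  stopifnot(ncol(scores) == N, top_n >= 1)
  y <- dataset_labels(dataset)
  if (length(unique(y)) < 2) stopf("dataset must contain both classes")
  conn_score <- (scores + t(scores)) / 2
  ut <- which(upper.tri(conn_score), arr.ind = TRUE)
  ord <- order(-conn_score[ut], ut[, 1], ut[, 2])
  take <- ut[ord[seq_len(min(top_n, nrow(ut)))], , drop = FALSE]
  # per-sample signed connection values
  vals <- vapply(dataset, function(g) g$features[take], numeric(nrow(take)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  rows <- lapply(seq_len(nrow(take)), function(r) {
    v1 <- vals[r, y == 1]; v0 <- vals[r, y == 0]
    p <- if (length(v1) < 2 || length(v0) < 2) NA_real_
    else if (sd(v1) == 0 && sd(v0) == 0) {
      if (mean(v1) == mean(v0)) 1 else 0
    } else tryCatch(t.test(v1, v0, var.equal = var_equal)$p.value,
                    error = function(e) NA_real_)
    data.frame(node_i = take[r, 1], node_j = take[r, 2],
               score = conn_score[take[r, 1], take[r, 2]],
               mean_class1 = mean(v1), mean_class0 = mean(v0),
               difference = mean(v1) - mean(v0), p_value = p)
  })
  do.call(rbind, rows)
}
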