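#' Generate a labelled synthetic weighted-graph dataset
#'
#' Emulates the benchmark used to validate the attention-pooling classifier
#' on a dataset larger than typical neuroimaging cohorts. Each graph is a
#' complete graph on `n_nodes` nodes with i.i.d. uniform edge weights. One
#' subset of `n_selected` nodes is drawn once per dataset (seeded) and
#' reused for every graph; for each graph
#' \deqn{W_1 = \sum_{i<j, i,j \in S} w_{ij}, \quad
#'       W_2 = \sum_{i \in S, j \notin S} w_{ij}, \quad
#'       W_0 = 2 W_1 + W_2,}
#' and the label is 1 ("Class-one") iff the graph's \eqn{W_0} is strictly
#' larger than the dataset-wide mean of \eqn{W_0}, else 0. Node features are
#' the rows of the weight matrix with the diagonal set to 1, mirroring the
#' self-correlation of connectivity matrices, so every downstream stage sees
#' the same data layout as a real connectivity graph. The diagonal is
#' excluded from the \eqn{W_1}/\eqn{W_2} sums.
#'
#' The label is therefore a fixed linear functional of the edge weights
#' thresholded at its empirical mean: the within-subset weights count twice
#' as much as the cross weights, which is the ground truth the
#' interpretation stage is expected to recover.
#'
#' @param n_graphs number of graphs (default 4000).
#' @param n_nodes nodes per graph (default 30).
#' @param n_selected size of the distinguished node subset (default 15).
#' @param seed integer seed; the subset draw and every edge weight flow
#'   from it.
#' @param weight_range lower/upper bound of the uniform edge-weight
#'   distribution (default `c(0, 1)`).
#' @return A `graph_dataset` (list of [new_graph_sample()] objects) with
#'   attributes `selected_nodes` (integer vector), `w0` (per-graph
#'   statistic), `w0_mean`, and `n_nodes`.
#' @examples
#' d <- synthetic_graphs(n_graphs = 20, n_nodes = 8, n_selected = 4, seed = 1)
#' table(dataset_labels(d))
#' @export
synthetic_graphs <- function(n_graphs = 4000, n_nodes = 30, n_selected = 15,
                             seed = 1, weight_range = c(0, 1)) {
  if (n_selected <= 0 || n_selected >= n_nodes)
    stopf("n_selected must satisfy 0 < n_selected < n_nodes")
  if (n_graphs < 2) stopf("need at least 2 graphs")
  if (length(weight_range) != 2 || weight_range[1] >= weight_range[2])
    stopf("weight_range must be c(low, high) with low < high")
  with_seed(seed, {
    selected <- sort(sample.int(n_nodes, n_selected))
    in_sel <- seq_len(n_nodes) %in% selected
    n_upper <- n_nodes * (n_nodes - 1) / 2
    iu <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    within_sel <- in_sel[iu[, 1]] & in_sel[iu[, 2]]
    cross_sel <- xor(in_sel[iu[, 1]], in_sel[iu[, 2]])
    graphs <- vector("list", n_graphs)
    w0 <- numeric(n_graphs)
    for (i in seq_len(n_graphs)) {
      w <- runif(n_upper, weight_range[1], weight_range[2])
      W <- matrix(0, n_nodes, n_nodes)
      W[upper.tri(W)] <- w
      W <- W + t(W)
      diag(W) <- 1
      w1 <- sum(w[within_sel])
      w2 <- sum(w[cross_sel])
      w0[i] <- 2 * w1 + w2
      graphs[[i]] <- new_graph_sample(features = W, adj = W, label = 0L,
                                      sample_id = sprintf("g%05d", i))
    }
    w0_mean <- mean(w0)
    for (i in seq_len(n_graphs))
      graphs[[i]]$label <- as.integer(w0[i] > w0_mean)
    structure(graphs, class = "graph_dataset",
              selected_nodes = selected, w0 = w0, w0_mean = w0_mean,
              n_nodes = n_nodes)
  })
}

#' Assemble graph samples into a dataset
#'
#' @param graphs list of `graph_sample` objects sharing one node count.
#' @return A `graph_dataset`.
#' @export
as_graph_dataset <- function(graphs) {
  if (!length(graphs)) stopf("empty dataset")
  if (!all(vapply(graphs, inherits, TRUE, "graph_sample")))
    stopf("all elements must be graph_sample objects")
  ns <- vapply(graphs, function(g) nrow(g$adj), 1L)
  if (length(unique(ns)) != 1)
    stopf("mixed node counts across samples: %s",
          paste(unique(ns), collapse = ", "))
  structure(graphs, class = "graph_dataset", n_nodes = ns[1])
}

#' @export
print.graph_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat(sprintf("graph_dataset: %d graphs, %d nodes, %d positive / %d negative\n",
              length(x), attr(x, "n_nodes"), sum(lab == 1), sum(lab == 0)))
  if (!is.null(attr(x, "selected_nodes")))
    cat("synthetic ground truth: selected nodes",
        paste(attr(x, "selected_nodes"), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.graph_dataset` <- function(x, i) {
  out <- unclass(x)[i]
  attrs <- attributes(x)
  structure(out, class = "graph_dataset",
            n_nodes = attrs$n_nodes,
            selected_nodes = attrs$selected_nodes,
            w0 = if (!is.null(attrs$w0)) attrs$w0[i] else NULL,
            w0_mean = attrs$w0_mean)
}

#' Labels of a graph dataset
#' @param dataset a `graph_dataset`.
#' @return Integer vector of 0/1 labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(g) g$label, 1L)
}

#' Flattened upper-triangle feature matrix of a dataset
#'
#' One row per graph, columns the strictly-upper-triangular entries of each
#' graph's node-feature matrix in row-major order - the representation fed
#' to the vector-input baselines (SVM, PCA+SVM, RF, MLP).
#'
#' @param dataset a `graph_dataset`.
#' @return Numeric matrix, n_graphs x N(N-1)/2.
#' @export
dataset_features <- function(dataset) {
  t(vapply(dataset, function(g) flatten_upper_triangle(g$features),
           numeric(attr(dataset, "n_nodes") * (attr(dataset, "n_nodes") - 1) / 2)))
}

#' Partition indices into cross-validation folds
#'
#' Deterministic under a fixed seed; folds are disjoint, exhaustive, and
#' their sizes differ by at most one.
#'
#' @param n number of samples (or a `graph_dataset`).
#' @param k number of folds (default 5).
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return List of k integer vectors of test indices.
#' @export
split_folds <- function(n, k = 5, seed = NULL) {
  if (inherits(n, "graph_dataset")) n <- length(n)
  n <- as.integer(n)
  if (k < 2) stopf("k must be at least 2")
  if (k > n) stopf("more folds (%d) than samples (%d)", k, n)
  perm <- with_seed(seed, sample.int(n))
  grp <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(i) sort(perm[grp == i]))
}
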