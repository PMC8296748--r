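#' Pearson connectivity matrix from region time series
#'
#' Computes the N x N matrix of pairwise Pearson correlation coefficients
#' between the mean time series of N regions of interest. This is the raw
#' substrate of every connectivity graph: its signed rows become node
#' features and its absolute values become edge weights.
#'
#' A region with constant (zero-variance) signal has no defined correlation
#' with anything; its off-diagonal entries are set to 0 with a warning so
#' that batch construction never aborts on one degenerate region.
#'
#' @param ts numeric matrix or data frame, T timepoints x N regions
#'   (column names are taken as region identifiers). T must be at least 3
#'   and N at least 2; missing values are rejected.
#' @return A `connectivity_matrix`: a symmetric numeric N x N matrix with
#'   unit diagonal, entries in `[-1, 1]`, and region ids as dimnames.
#' @seealso [build_graph()], [flatten_upper_triangle()]
#' @examples
#' ts <- matrix(rnorm(40), nrow = 10, ncol = 4,
#'              dimnames = list(NULL, paste0("r", 1:4)))
#' cm <- pearson_connectivity(ts)
#' @export
pearson_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stopf("time series must be numeric")
  if (anyNA(ts)) stopf("time series contains missing values")
  if (nrow(ts) < 3) stopf("need at least 3 timepoints, got %d", nrow(ts))
  if (ncol(ts) < 2) stopf("need at least 2 regions, got %d", ncol(ts))
  ids <- colnames(ts) %||% paste0("roi", seq_len(ncol(ts)))
  v <- apply(ts, 2, stats::var)
  rho <- suppressWarnings(stats::cor(ts))
  if (any(v == 0)) {
    bad <- which(v == 0)
    warnf("constant time series in region(s) %s; correlations set to 0",
          paste(ids[bad], collapse = ", "))
    rho[bad, ] <- 0
    rho[, bad] <- 0
  }
  diag(rho) <- 1
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  dimnames(rho) <- list(ids, ids)
  structure(rho, class = c("connectivity_matrix", "matrix", "array"))
}

#' Validate and classify a raw matrix as a connectivity matrix
#'
#' @param m square numeric matrix, symmetric within `tol`, unit diagonal
#'   within `tol`, entries in `[-1 - tol, 1 + tol]`. Small asymmetries are
#'   symmetrized by averaging.
#' @param region_ids optional character vector of region labels.
#' @param tol numeric tolerance for the symmetry/diagonal/range checks.
#' @return A `connectivity_matrix`.
#' @export
as_connectivity_matrix <- function(m, region_ids = NULL, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("matrix must be square, got %dx%d", nrow(m), ncol(m))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("NA entry at row %d, col %d", bad[1], bad[2])
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) stopf("matrix asymmetric beyond tolerance (max |m - t(m)| = %g)", asym)
  m <- (m + t(m)) / 2
  dbad <- which(abs(diag(m) - 1) > tol)
  if (length(dbad)) stopf("diagonal entry %d is %g, expected 1", dbad[1], diag(m)[dbad[1]])
  diag(m) <- 1
  out <- which(abs(m) > 1 + tol, arr.ind = TRUE)
  if (nrow(out)) stopf("entry %g at row %d, col %d outside [-1, 1]",
                       m[out[1, 1], out[1, 2]], out[1, 1], out[1, 2])
  m[m > 1] <- 1
  m[m < -1] <- -1
  ids <- region_ids %||% rownames(m) %||% paste0("roi", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("connectivity_matrix", "matrix", "array"))
}

#' Build a weighted graph sample from a connectivity matrix
#'
#' Node features are the *signed* rows of the connectivity matrix (each
#' node's connectivity profile with every region). Edge weights are the
#' absolute correlations; with a threshold `t`, only entries whose absolute
#' weight is strictly greater than `t` are retained, all others are zeroed.
#' Thresholding alters graph structure only - the feature rows are never
#' touched. Self-loops (the unit diagonal) count as edges and survive any
#' threshold below 1, so every node remains in its own neighborhood.
#'
#' @param cm a `connectivity_matrix` (or square symmetric matrix accepted by
#'   [as_connectivity_matrix()]).
#' @param label class label, 0 (control-like) or 1 (case-like).
#' @param threshold numeric in `[0, 1)`, or `NULL` to keep the dense graph.
#' @param sample_id identifier string.
#' @return A `graph_sample`: list with elements `features` (N x N signed),
#'   `adj` (N x N non-negative, zeroed below threshold), `label`,
#'   `sample_id`.
#' @examples
#' cm <- as_connectivity_matrix(diag(3) * 0 + diag(3) + 0)
#' g <- build_graph(as_connectivity_matrix(diag(3)), label = 0)
#' @export
build_graph <- function(cm, label, threshold = NULL, sample_id = "sample") {
  if (!inherits(cm, "connectivity_matrix")) cm <- as_connectivity_matrix(cm)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        threshold < 0 || threshold >= 1)
      stopf("threshold must be a single value in [0, 1) or NULL")
  }
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1")
  adj <- abs(unclass(cm))
  if (!is.null(threshold)) adj[adj <= threshold] <- 0
  new_graph_sample(features = unclass(cm), adj = adj,
                   label = as.integer(label), sample_id = sample_id)
}

#' Construct a graph sample from explicit components
#'
#' @param features N x F signed numeric matrix of node features.
#' @param adj N x N symmetric non-negative adjacency weights in `[0, 1]`.
#' @param label 0 or 1.
#' @param sample_id identifier string.
#' @return A `graph_sample`.
#' @export
new_graph_sample <- function(features, adj, label, sample_id = "sample") {
  features <- as.matrix(features)
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stopf("adjacency must be square")
  if (nrow(features) != nrow(adj)) stopf("features/adjacency node count mismatch")
  if (any(adj < 0) || any(adj > 1)) stopf("adjacency weights must lie in [0, 1]")
  if (max(abs(adj - t(adj))) > 1e-8) stopf("adjacency must be symmetric")
  structure(list(features = features, adj = adj,
                 label = as.integer(label), sample_id = sample_id),
            class = "graph_sample")
}

#' @export
print.graph_sample <- function(x, ...) {
  cat(sprintf("graph_sample '%s': %d nodes, %d features, label %d, %d edges\n",
              x$sample_id, nrow(x$adj), ncol(x$features), x$label, edge_count(x)))
  invisible(x)
}

#' Neighbor index sets of a graph sample
#'
#' @param g a `graph_sample`.
#' @return List of integer vectors; element i holds the indices j with a
#'   nonzero adjacency entry (i, j), node i itself included whenever the
#'   diagonal survived thresholding.
#' @export
neighbor_sets <- function(g) {
  stopifnot(inherits(g, "graph_sample"))
  apply(g$adj > 0, 1, which, simplify = FALSE)
}

#' Number of nonzero adjacency entries
#'
#' Counts all nonzero entries of the adjacency matrix, diagonal included,
#' so a dense N-node graph has N^2 edges (12,100 for N = 110).
#'
#' @param g a `graph_sample`.
#' @return Integer count.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "graph_sample"))
  sum(g$adj != 0)
}

#' Sparsity of a graph sample
#'
#' Fraction of adjacency entries zeroed by thresholding, relative to the
#' dense count N^2. A dense graph has sparsity 0.
#'
#' @param g a `graph_sample`.
#' @return Numeric in `[0, 1]`.
#' @export
graph_sparsity <- function(g) {
  stopifnot(inherits(g, "graph_sample"))
  n <- nrow(g$adj)
  1 - edge_count(g) / n^2
}

#' Flatten the strictly upper triangle of a connectivity matrix
#'
#' Extracts the above-diagonal entries in fixed row-major order
#' (row 1: columns 2..N, row 2: columns 3..N, ...), giving the
#' N(N-1)/2-dimensional feature vector used by the vector-input models
#' (5995 dimensions for N = 110).
#'
#' @param cm square matrix (connectivity matrix or a graph's feature matrix).
#' @return Numeric vector of length N(N-1)/2.
#' @export
flatten_upper_triangle <- function(cm) {
  m <- as.matrix(cm)
  n <- nrow(m)
  if (n != ncol(m) || n < 2) stopf("need a square matrix with N >= 2")
  t(m)[lower.tri(m)]
}
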