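# Readers and writers for the plain-text interchange formats: N x N
# connectivity CSV (header + row labels), T x N time-series TSV/CSV
# (header = region ids), dataset manifest CSV, mask CSV.

#' Write a connectivity matrix to CSV
#'
#' Values are serialized with 17 significant digits so a read/write
#' round trip is lossless.
#'
#' @param cm a `connectivity_matrix` (or square matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  m <- as.matrix(cm)
  df <- data.frame(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  rownames(df) <- rownames(m) %||% paste0("roi", seq_len(nrow(m)))
  colnames(df) <- colnames(m) %||% rownames(df)
  write.csv(df, path, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from CSV
#'
#' Validates shape, symmetry (small asymmetries are symmetrized by
#' averaging, larger ones rejected), unit diagonal and the `[-1, 1]`
#' range; failures report the offending location.
#'
#' @param path CSV file with header and row labels.
#' @param tol validation tolerance (default 1e-8).
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, tol = 1e-8) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric cells in %s", path)
  as_connectivity_matrix(m, region_ids = rownames(df), tol = tol)
}

#' Read a region time-series table
#'
#' @param path TSV (default) or CSV file, T rows x N region columns with a
#'   header row of region ids.
#' @param sep field separator; inferred from the file extension when
#'   `NULL` (`.csv` comma, otherwise tab).
#' @return Numeric matrix with region ids as column names.
#' @export
read_timeseries <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.csv(path, sep = sep, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric cells in %s", path)
  if (anyNA(m)) stopf("missing values in %s", path)
  m
}

#' Load a graph dataset from a manifest
#'
#' The manifest is a CSV with columns `sample_id`, `path`, `label` and an
#' optional `format` column (`"matrix"`, the default, or `"timeseries"`;
#' time-series rows run the full construction pipeline: Pearson
#' connectivity, absolute-value edge weights, optional thresholding).
#' Paths are resolved relative to the manifest's directory. All samples
#' must share one node count; samples are returned in manifest order.
#'
#' @param manifest path to the manifest CSV, or an equivalent data frame
#'   (paths then resolved relative to `root`).
#' @param threshold optional sparsification threshold passed to
#'   [build_graph()].
#' @param root base directory for relative paths (defaults to the
#'   manifest's directory).
#' @return A `graph_dataset`.
#' @export
load_dataset <- function(manifest, threshold = NULL, root = NULL) {
  if (is.character(manifest)) {
    root <- root %||% dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  root <- root %||% "."
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stopf("duplicate sample_id in manifest")
  if (!all(manifest$label %in% c(0, 1)))
    stopf("labels must be 0 or 1")
  fmt <- manifest$format %||% rep("matrix", nrow(manifest))
  graphs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(root, manifest$path[i])
    if (!file.exists(p))
      stopf("manifest row %d ('%s'): file not found: %s",
            i, manifest$sample_id[i], manifest$path[i])
    cm <- if (fmt[i] == "timeseries") pearson_connectivity(read_timeseries(p))
          else read_connectivity(p)
    build_graph(cm, label = manifest$label[i], threshold = threshold,
                sample_id = manifest$sample_id[i])
  })
  as_graph_dataset(graphs)
}

#' Write a graph dataset as per-sample CSVs plus a manifest
#'
#' Emits one connectivity CSV per graph, a `manifest.csv`, and - when the
#' dataset carries synthetic ground truth - a `ground_truth.json` with the
#' selected node subset and the labelling statistics.
#'
#' @param dataset a `graph_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(g) {
    fn <- paste0(g$sample_id, ".csv")
    write_connectivity(g$features, file.path(dir, fn))
    data.frame(sample_id = g$sample_id, path = fn, label = g$label)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  sel <- attr(dataset, "selected_nodes")
  if (!is.null(sel) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(selected_nodes = sel, w0_mean = attr(dataset, "w0_mean"),
           w0 = attr(dataset, "w0")),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write / read a feature importance mask
#'
#' @param mask N x F matrix (a `feature_mask` or saliency score matrix).
#' @param path CSV file.
#' @return `path` invisibly / the mask matrix.
#' @export
write_mask <- function(mask, path) {
  write.csv(format(unclass(as.matrix(mask)), digits = 17, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  dimnames(m) <- NULL
  m
}
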