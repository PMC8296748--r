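#' Save / load a fitted graph network as a plain-text checkpoint
#'
#' A checkpoint is a pair of text files: `<prefix>_config.json` holding
#' the architecture description and `<prefix>_theta.csv` holding the flat
#' parameter vector at full precision.
#'
#' @param model a `gatnet`.
#' @param prefix file path prefix.
#' @return `prefix` invisibly / the restored `gatnet`.
#' @export
gat_save <- function(model, prefix) {
  stopifnot(inherits(model, "gatnet"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("checkpointing requires the jsonlite package")
  cfg <- model$config
  keep <- c("n_nodes", "in_dim", "model", "heads", "units", "combine_str",
            "activation_str", "gcn_units", "cheby_order", "fc_units",
            "lrelu_slope", "attn_slope", "edge_weighted_attention")
  jsonlite::write_json(cfg[keep], paste0(prefix, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(theta = format(model$theta, digits = 17, trim = TRUE)),
                     paste0(prefix, "_theta.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}

#' @rdname gat_save
#' @export
gat_load <- function(prefix) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("checkpointing requires the jsonlite package")
  cj <- jsonlite::read_json(paste0(prefix, "_config.json"), simplifyVector = TRUE)
  cfg <- gat_config(n_nodes = cj$n_nodes, in_dim = cj$in_dim, model = cj$model,
                    heads = cj$heads, units = cj$units,
                    combine = if (length(cj$combine_str)) cj$combine_str,
                    activation = if (length(cj$activation_str)) cj$activation_str,
                    gcn_units = cj$gcn_units, cheby_order = cj$cheby_order,
                    fc_units = cj$fc_units, lrelu_slope = cj$lrelu_slope,
                    attn_slope = cj$attn_slope,
                    edge_weighted_attention = cj$edge_weighted_attention)
  theta <- read.csv(paste0(prefix, "_theta.csv"))$theta
  net <- gat_network(cfg, theta = theta)
  net$trained <- TRUE
  net
}
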