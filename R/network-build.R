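# Assembly of temporal multilayer networks from occurrence / trait matrices.
#
# Layers are ordered time bins.  Physical nodes are samples plus taxa (or
# traits).  A sample exists in exactly one layer and has a single state
# node; a taxon/trait has one state node per layer in which it occurs.
# Within each layer the network is bipartite: edges link sample state nodes
# to taxon/trait state nodes.  Interlayer links are never materialized; they
# arise from the relax process during clustering.

new_multilayer <- function(nodes, state_nodes, edges, n_layers, kind,
                           relax_rate = NA_real_, relax_limit = NA_integer_,
                           span_max = NA_real_, bin_width = NA_real_) {
  net <- structure(list(nodes = nodes, state_nodes = state_nodes, edges = edges,
                        n_layers = as.integer(n_layers), kind = kind,
                        relax_rate = relax_rate, relax_limit = relax_limit,
                        span_max = span_max, bin_width = bin_width),
                   class = "multilayer_network")
  validate_multilayer(net)
}

#' Validate a multilayer network's structural invariants
#'
#' Checks within-layer bipartiteness (every edge links a sample node to a
#' taxon/trait node in the same layer), positive edge weights, single state
#' nodes for samples, and that every edge endpoint has a matching state node.
#'
#' @param net a `multilayer_network`.
#' @return `net`, invisibly-validated (errors on violation).
#' @export
validate_multilayer <- function(net) {
  nodes <- net$nodes; sn <- net$state_nodes; e <- net$edges
  role <- nodes$role[match(e$from, nodes$id)]
  role2 <- nodes$role[match(e$to, nodes$id)]
  if (anyNA(role) || anyNA(role2))
    stop("multilayer network: edge references an unknown node id")
  if (any(role != "sample") || any(role2 == "sample"))
    stop("multilayer network: bipartite violation (edges must link a sample to a taxon/trait)")
  if (any(e$weight <= 0)) stop("multilayer network: all edge weights must be > 0")
  if (any(e$layer < 0) || any(e$layer >= net$n_layers))
    stop("multilayer network: edge layer out of range")
  key_sn <- paste(sn$node_id, sn$layer)
  if (anyDuplicated(key_sn)) stop("multilayer network: duplicated state node")
  if (!all(paste(e$from, e$layer) %in% key_sn) ||
      !all(paste(e$to, e$layer) %in% key_sn))
    stop("multilayer network: edge endpoint without a state node in its layer")
  n_states_sample <- table(factor(sn$node_id[sn$node_id %in% nodes$id[nodes$role == "sample"]]))
  if (length(n_states_sample) && any(n_states_sample != 1))
    stop("multilayer network: sample physical nodes must have exactly one state node")
  net
}

build_bipartite_multilayer <- function(mat, samples, kind, feature_role,
                                       n_layers = NULL) {
  if (nrow(mat) == 0 || ncol(mat) == 0 || all(mat == 0))
    stop("build network: empty matrix")
  stopifnot(all(rownames(mat) %in% samples$sample_id))
  layer <- samples$layer[match(rownames(mat), samples$sample_id)]
  if (anyNA(layer)) stop("build network: all samples need layer assignments")
  if (is.null(n_layers))
    n_layers <- attr(samples, "n_layers") %||% (max(layer) + 1L)
  # drop features absent from every (filtered) sample
  present <- colSums(mat != 0) > 0
  mat <- mat[, present, drop = FALSE]
  n_s <- nrow(mat); n_f <- ncol(mat)
  nodes <- data.frame(
    id = seq_len(n_s + n_f),
    name = c(rownames(mat), colnames(mat)),
    role = c(rep("sample", n_s), rep(feature_role, n_f)),
    stringsAsFactors = FALSE)
  idx <- which(mat != 0, arr.ind = TRUE)
  edges <- data.frame(layer = layer[idx[, 1]],
                      from = idx[, 1],
                      to = n_s + idx[, 2],
                      weight = mat[idx])
  edges <- edges[order(edges$layer, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  feat_states <- unique(edges[, c("to", "layer")])
  sn <- rbind(data.frame(node_id = seq_len(n_s), layer = layer),
              data.frame(node_id = feat_states$to, layer = feat_states$layer))
  sn <- sn[order(sn$node_id, sn$layer), , drop = FALSE]
  sn$state_id <- seq_len(nrow(sn))
  rownames(sn) <- NULL
  new_multilayer(nodes, sn[, c("state_id", "node_id", "layer")], edges,
                 n_layers, kind,
                 span_max = attr(samples, "span_max") %||% NA_real_,
                 bin_width = attr(samples, "bin_width") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the taxonomic multilayer network
#'
#' One unweighted (weight 1) intralayer edge per species presence; physical
#' nodes are the samples plus the taxa occurring in at least one sample.
#'
#' @param occ binary sample x species matrix.
#' @param samples data frame of the matrix's samples with a `layer` column
#'   (see [assign_layers()]).
#' @param n_layers total number of layers; defaults to the `n_layers`
#'   attribute of `samples`.
#' @return A `multilayer_network` of kind `"taxonomic"`.
#' @export
build_taxonomic_network <- function(occ, samples, n_layers = NULL) {
  occ <- (occ != 0) * 1
  build_bipartite_multilayer(occ, samples, "taxonomic", "taxon", n_layers)
}

#' Build the trait multilayer network
#'
#' One weighted intralayer edge per nonzero (sample, trait) weight; physical
#' nodes are the samples plus the traits.
#'
#' @param trait_weights numeric sample x trait matrix in \[0, 1\] (see
#'   [build_trait_weights()]).
#' @inheritParams build_taxonomic_network
#' @return A `multilayer_network` of kind `"trait"`.
#' @export
build_trait_network <- function(trait_weights, samples, n_layers = NULL) {
  build_bipartite_multilayer(trait_weights, samples, "trait", "trait", n_layers)
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("multilayer network (%s): n = %d physical nodes (%d samples, %d %s), m = %d intralayer links, t = %d layers\n",
              x$kind, nrow(x$nodes), sum(x$nodes$role == "sample"),
              sum(x$nodes$role != "sample"),
              if (x$kind == "trait") "traits" else "taxa",
              nrow(x$edges), x$n_layers))
  invisible(x)
}

#' Structural summary (n, m, t) of a multilayer network
#'
#' @param net a `multilayer_network`.
#' @return List with `n` (physical nodes), `m` (intralayer links), `t`
#'   (layers), `n_samples`, `n_features`, `n_state_nodes`.
#' @export
network_size <- function(net) {
  list(n = nrow(net$nodes), m = nrow(net$edges), t = net$n_layers,
       n_samples = sum(net$nodes$role == "sample"),
       n_features = sum(net$nodes$role != "sample"),
       n_state_nodes = nrow(net$state_nodes))
}

#' Node table of a multilayer network
#'
#' @param net a `multilayer_network`.
#' @return Data frame (node id, role, label, comma-separated layer list).
#' @export
node_table <- function(net) {
  layers <- vapply(net$nodes$id, function(i) {
    paste(sort(net$state_nodes$layer[net$state_nodes$node_id == i]), collapse = ",")
  }, character(1))
  data.frame(id = net$nodes$id, role = net$nodes$role, label = net$nodes$name,
             layers = layers, stringsAsFactors = FALSE)
}
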